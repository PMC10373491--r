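## Shared fixtures, built in code.

## Tiny two-position hotspot set over a four-letter alphabet.
tiny_hotspots <- function(alphabet = c("A", "C", "D", "E")) {
  hotspot_set(position = c(3L, 7L), wt = c("A", "C"), chain = "",
              alphabet = alphabet)
}

## Seeded random residue selection of n residues (includes the tiny
## hotspots at positions 3 and 7 when n >= 8).
tiny_selection <- function(n = 8, seed = 42) {
  stopifnot(n >= 8)
  coords <- with_seed_local(seed, matrix(rnorm(n * 3, sd = 5), n, 3))
  aa <- c("L", "G", "A", "T", "D", "H", "C", "S",
          rep("G", max(0, n - 8)))[seq_len(n)]
  residue_selection(position = seq_len(n), chain = "", aa = aa,
                    coords = coords)
}

## Run expr under a seed without disturbing the session RNG.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Small random symmetric positive weight matrix with zero diagonal.
random_weights <- function(n, seed = 1) {
  W <- with_seed_local(seed, matrix(abs(rnorm(n * n)) + 0.1, n, n))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

## The bundled demo context (23-residue site, 20-property table).
demo_context <- function() {
  list(hotspots = demo_hotspots(),
       selection = read_selection_tsv(),
       table = load_property_table())
}
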