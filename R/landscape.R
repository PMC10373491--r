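## Seeded epistatic sequence-energy landscapes.  These stand in for an
## external physics-based labeling pipeline: each variant's energy is a
## baseline plus additive per-site effects, plus pairwise epistatic couplings
## on a seeded subset of position pairs, plus optional Gaussian noise.  The
## sign convention follows binding-energy scores: more negative = better.

#' Generate a random epistatic fitness landscape
#'
#' Additive effects are drawn i.i.d. N(0, 1) for every non-wild-type letter
#' of the alphabet at every hotspot (wild-type effects are zero by
#' definition).  A seeded fraction of hotspot pairs receives pairwise
#' coupling tables drawn N(0, 1); when `distance_scale = TRUE` each pair's
#' couplings are multiplied by the inverse Calpha distance between the two
#' hotspot residues (normalized to mean 1 over hotspot pairs), tying the
#' epistatic signal to the binding-site geometry.
#'
#' @param hotspots A [hotspot_set()].
#' @param epistatic_fraction Fraction of the `C(N_hot, 2)` position pairs
#'   that carry couplings (0 = purely additive).
#' @param sigma Standard deviation of the per-variant Gaussian label noise
#'   (same units as the energy), >= 0.
#' @param seed Integer seed; generation is fully reproducible.
#' @param baseline Wild-type energy (default -10, binding-energy-like).
#' @param selection Optional [residue_selection()]; required when
#'   `distance_scale = TRUE`.
#' @param distance_scale Couple epistatic magnitudes to inverse pair
#'   distance (default `FALSE`).
#' @return An object of class `landscape`: baseline, additive effect matrix
#'   (N_hot x 20, columns in one-letter alphabetical order), coupling
#'   tables, noise sigma and seed.
#' @export
generate_landscape <- function(hotspots, epistatic_fraction = 0, sigma = 0,
                               seed = 1L, baseline = -10,
                               selection = NULL, distance_scale = FALSE) {
  stopifnot(inherits(hotspots, "hotspot_set"),
            epistatic_fraction >= 0, epistatic_fraction <= 1, sigma >= 0)
  n_hot <- length(hotspots)
  wt <- hotspots$positions$wt
  alpha <- hotspots$alphabet
  with_local_seed(hash_seed("landscape", seed), {
    additive <- matrix(0, n_hot, 20, dimnames = list(hotspots$positions$label,
                                                     AA_ALPHABET))
    for (j in seq_len(n_hot)) {
      letters <- setdiff(alpha, wt[j])
      additive[j, letters] <- rnorm(length(letters))
    }
    pairs <- utils::combn(n_hot, 2)
    n_pairs <- ncol(pairs)
    n_coupled <- round(epistatic_fraction * n_pairs)
    coupled <- if (n_coupled > 0) {
      sort(sample.int(n_pairs, n_coupled))
    } else {
      integer(0)
    }
    pair_w <- rep(1, n_pairs)
    if (distance_scale) {
      if (is.null(selection)) {
        abort("`selection` is required for distance-scaled couplings")
      }
      node_idx <- hotspot_node_index(hotspots, selection)
      invd <- edge_weights(selection)[node_idx, node_idx]
      w <- invd[cbind(pairs[1, ], pairs[2, ])]
      pair_w <- w / mean(w)
    }
    couplings <- list()
    for (k in coupled) {
      i <- pairs[1, k]; j <- pairs[2, k]
      cm <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
      li <- setdiff(alpha, wt[i]); lj <- setdiff(alpha, wt[j])
      cm[li, lj] <- rnorm(length(li) * length(lj)) * pair_w[k]
      couplings[[paste0(i, ":", j)]] <- cm
    }
    structure(
      list(baseline = baseline, additive = additive, couplings = couplings,
           noise_sigma = sigma, seed = as.integer(seed),
           positions = hotspots$positions, alphabet = alpha,
           distance_scale = distance_scale),
      class = "landscape"
    )
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", nrow(x$additive), " positions, ",
      length(x$couplings), " coupled pairs, sigma = ", x$noise_sigma,
      ", baseline = ", x$baseline, "\n", sep = "")
  invisible(x)
}

## Occupant letter indices (into AA_ALPHABET) for an assignment matrix.
occupant_letters <- function(assignments, hotspots) {
  if (is.null(dim(assignments))) {
    assignments <- matrix(as.integer(assignments), nrow = 1)
  }
  wt_idx <- match(hotspots$positions$wt, AA_ALPHABET)
  occ <- matrix(rep(wt_idx, each = nrow(assignments)),
                nrow = nrow(assignments))
  for (j in seq_len(ncol(assignments))) {
    hit <- assignments[, j] > 0
    occ[hit, j] <- match(hotspots$alphabet[assignments[hit, j]], AA_ALPHABET)
  }
  occ
}

#' Score variants on a landscape
#'
#' Energy = baseline + sum of additive effects + sum of pairwise couplings
#' (+ Gaussian noise when the landscape has `noise_sigma > 0`).  Noise is
#' drawn from a stream seeded by the variant's canonical name, so repeated
#' scoring of the same variant always returns the same value.
#'
#' @param params A [generate_landscape()] result.
#' @param variants Character vector of variant names, or an assignment
#'   matrix as produced by [parse_variants()] / [enumerate_assignments()].
#' @param hotspots The [hotspot_set()] the landscape was generated for.
#' @return Numeric energy vector.
#' @export
score_variants <- function(params, variants, hotspots) {
  stopifnot(inherits(params, "landscape"))
  if (is.character(variants)) {
    names_chr <- variants
    assignments <- parse_variants(variants, hotspots)
  } else {
    assignments <- variants
    if (is.null(dim(assignments))) {
      assignments <- matrix(as.integer(assignments), nrow = 1)
    }
    names_chr <- format_variants(assignments, hotspots)
  }
  if (ncol(assignments) != nrow(params$additive)) {
    abort("variant has positions outside the landscape's hotspot set")
  }
  occ <- occupant_letters(assignments, hotspots)
  e <- rep(params$baseline, nrow(occ))
  for (j in seq_len(ncol(occ))) {
    e <- e + params$additive[j, occ[, j]]
  }
  for (key in names(params$couplings)) {
    ij <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    cm <- params$couplings[[key]]
    e <- e + cm[cbind(occ[, ij[1]], occ[, ij[2]])]
  }
  if (params$noise_sigma > 0) {
    noise <- vapply(names_chr, function(nm) {
      with_local_seed(hash_seed(nm, params$seed), rnorm(1, 0, params$noise_sigma))
    }, numeric(1), USE.NAMES = FALSE)
    e <- e + noise
  }
  unname(e)
}

#' @rdname score_variants
#' @export
score_variant <- function(params, variants, hotspots) {
  score_variants(params, variants, hotspots)
}

#' Simulate a labeled mutant library
#'
#' Samples a library with [sample_library()] and labels every variant with
#' its landscape energy, emulating an externally labeled training set.
#'
#' @inheritParams score_variants
#' @param l_max Maximum mutant order of the sample.
#' @param n Library size.
#' @param seed Integer seed (governs the sample; label noise is tied to the
#'   landscape's own seed).
#' @return A tibble with `variant_name` and `energy`; the landscape is
#'   attached as attribute `"truth"` and the assignment matrix as
#'   `"assignments"`.
#' @export
make_dataset <- function(params, hotspots, l_max, n, seed) {
  lib <- sample_library(hotspots, l_max, n, seed = hash_seed("dataset", seed))
  assignments <- attr(lib, "assignments")
  lib$energy <- score_variants(params, assignments, hotspots)
  attr(lib, "assignments") <- assignments
  attr(lib, "truth") <- params
  lib
}

#' Persist a landscape to JSON (exact reproducibility artifact)
#'
#' @param params A [generate_landscape()] result.
#' @param path JSON file path.
#' @return `read_landscape()` returns the `landscape`; `write_landscape()`
#'   returns `path` invisibly.
#' @export
write_landscape <- function(params, path) {
  stopifnot(inherits(params, "landscape"))
  obj <- list(
    baseline = params$baseline,
    noise_sigma = params$noise_sigma,
    seed = params$seed,
    distance_scale = params$distance_scale,
    alphabet = params$alphabet,
    positions = params$positions[, c("position", "chain", "wt")],
    additive = params$additive,
    couplings = params$couplings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  additive <- as.matrix(obj$additive)
  colnames(additive) <- AA_ALPHABET
  couplings <- lapply(obj$couplings, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
    m
  })
  pos <- tibble::as_tibble(obj$positions)
  pos$chain[is.na(pos$chain)] <- ""
  pos$label <- paste0(pos$wt, pos$position, pos$chain)
  rownames(additive) <- pos$label
  structure(
    list(baseline = obj$baseline, additive = additive,
         couplings = couplings, noise_sigma = obj$noise_sigma,
         seed = as.integer(obj$seed), positions = pos,
         alphabet = obj$alphabet, distance_scale = isTRUE(obj$distance_scale)),
    class = "landscape"
  )
}
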