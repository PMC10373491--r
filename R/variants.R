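## Variants are stored internally as integer "assignment" vectors over the
## hotspot positions: 0 = position not part of the assignment (wild type),
## k > 0 = the k-th alphabet letter assigned to that position.  Following the
## combinatorial-space counting convention C(N_hot, L) * |AA|^L, an assigned
## letter is allowed to equal the wild-type letter, so the effective mutational
## order of an assignment can be lower than the number of assigned positions.

variant_token_rx <- "^([A-Z])([0-9]+)([′']?)([A-Z])$"

#' Parse a variant name against a hotspot set
#'
#' Variant names are underscore-joined tokens of the form
#' `<wt><position><mut>`, e.g. `"F85A_W57F_Y150F"`; a trailing apostrophe (or
#' prime mark) after the position selects the primed chain (`F85'A`).  The
#' wild-type sentinel `"WT"` (or an empty string) denotes the unmutated
#' enzyme.  Wild-type letters are cross-checked against the hotspot set.
#'
#' @param name Character scalar variant name.
#' @param hotspots A [hotspot_set()].
#' @return An integer assignment vector of class `variant` (one entry per
#'   hotspot; 0 = untouched, otherwise an index into the alphabet).
#' @examples
#' hs <- hotspot_set(c(19, 57, 150, 85), c("F", "W", "Y", "F"),
#'                   chain = c("", "", "", "'"))
#' v <- parse_variant_name("F85A_W57F_Y150F", hs)
#' variant_order(v, hs)
#' @export
parse_variant_name <- function(name, hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  pos_tbl <- hotspots$positions
  assign <- integer(nrow(pos_tbl))
  name <- trimws(name)
  if (identical(name, "") || identical(toupper(name), "WT")) {
    return(structure(assign, class = "variant"))
  }
  tokens <- strsplit(name, "_", fixed = TRUE)[[1]]
  for (tok in tokens) {
    m <- regmatches(tok, regexec(variant_token_rx, tok))[[1]]
    if (length(m) == 0) {
      abort(paste0("malformed variant token: '", tok, "'"))
    }
    wt <- m[2]; pos <- as.integer(m[3]); tag <- m[4]; mut <- m[5]
    if (tag == "′") tag <- "'"
    if (tag == "") {
      hits <- which(pos_tbl$position == pos)
      if (length(hits) > 1) {
        abort(paste0("ambiguous token '", tok,
                     "': position ", pos, " exists on more than one chain"))
      }
    } else {
      hits <- which(pos_tbl$position == pos & pos_tbl$chain == tag)
    }
    if (length(hits) == 0) {
      abort(paste0("unknown hotspot position in token '", tok, "'"))
    }
    if (pos_tbl$wt[hits] != wt) {
      abort(paste0("wild-type mismatch in token '", tok, "': hotspot ",
                   pos_tbl$label[hits], " has wild type ", pos_tbl$wt[hits]))
    }
    k <- match(mut, hotspots$alphabet)
    if (is.na(k)) {
      abort(paste0("target letter '", mut, "' in token '", tok,
                   "' is not in the alphabet"))
    }
    if (assign[hits] != 0) {
      abort(paste0("duplicate substitution at hotspot ", pos_tbl$label[hits]))
    }
    assign[hits] <- k
  }
  structure(assign, class = "variant")
}

#' Parse many variant names into an assignment matrix
#'
#' @param names Character vector of variant names.
#' @inheritParams parse_variant_name
#' @return Integer matrix (length(names) x n_hotspots).
#' @export
parse_variants <- function(names, hotspots) {
  out <- matrix(0L, nrow = length(names), ncol = length(hotspots))
  for (i in seq_along(names)) {
    out[i, ] <- as.integer(parse_variant_name(names[i], hotspots))
  }
  rownames(out) <- names
  out
}

#' Format assignments as canonical variant names
#'
#' The canonical form lists one token per assigned position in hotspot order
#' (including assignments to the wild-type letter, e.g. `F19F`, which the
#' combinatorial counting convention treats as distinct library members);
#' an empty assignment formats as `"WT"`.
#'
#' @param assignments Integer assignment matrix (n x n_hotspots) or a single
#'   `variant` vector.
#' @inheritParams parse_variant_name
#' @return Character vector of canonical names.
#' @export
format_variants <- function(assignments, hotspots) {
  if (is.null(dim(assignments))) {
    assignments <- matrix(as.integer(assignments), nrow = 1)
  }
  pos_tbl <- hotspots$positions
  n <- nrow(assignments)
  tok <- matrix("", nrow = n, ncol = ncol(assignments))
  for (j in seq_len(ncol(assignments))) {
    aj <- assignments[, j]
    hit <- aj > 0
    tok[hit, j] <- paste0(pos_tbl$wt[j], pos_tbl$position[j], pos_tbl$chain[j],
                          hotspots$alphabet[aj[hit]])
  }
  nm <- do.call(paste, c(split(tok, col(tok)), list(sep = "_")))
  nm <- gsub("_+", "_", nm)
  nm <- gsub("^_|_$", "", nm)
  nm[nm == ""] <- "WT"
  nm
}

#' @rdname format_variants
#' @export
format.variant <- function(x, hotspots, ...) {
  format_variants(x, hotspots)
}

#' Mutational order of a variant
#'
#' The order L counts substitutions whose target letter differs from the
#' wild-type letter (an assignment of the wild-type letter does not raise the
#' order).
#'
#' @param variant A `variant` assignment vector or assignment matrix.
#' @inheritParams parse_variant_name
#' @return Integer vector of orders.
#' @export
variant_order <- function(variant, hotspots) {
  if (is.null(dim(variant))) variant <- matrix(as.integer(variant), nrow = 1)
  wt_idx <- match(hotspots$positions$wt, hotspots$alphabet)
  ord <- integer(nrow(variant))
  for (j in seq_len(ncol(variant))) {
    aj <- variant[, j]
    ord <- ord + as.integer(aj > 0 & (is.na(wt_idx[j]) | aj != wt_idx[j]))
  }
  ord
}

#' Size of a combinatorial search space
#'
#' Computes `C(n_hot, l_max) * aa_count^l_max`: the number of ways to choose
#' `l_max` of the `n_hot` mutable positions and assign each any of the
#' `aa_count` allowed target amino acids (wild-type letters included).
#'
#' @param n_hot Number of hotspot positions.
#' @param l_max Mutant order (number of positions chosen).
#' @param aa_count Number of allowed target amino acids.
#' @return The exact count as a double (all supported spaces are far below
#'   2^53, so the value is exact).
#' @examples
#' search_space_size(4, 4, 20)  # 160000
#' search_space_size(8, 4, 20)  # 11.2 million
#' @export
search_space_size <- function(n_hot, l_max, aa_count) {
  stopifnot(n_hot >= 1, aa_count >= 1)
  if (l_max < 1 || l_max > n_hot) {
    abort("`l_max` must satisfy 1 <= l_max <= n_hot")
  }
  choose(n_hot, l_max) * as.numeric(aa_count)^l_max
}

#' Percentage of a search space covered by a library
#'
#' @param n_examples Number of library members.
#' @param space Search-space size.
#' @return `100 * n_examples / space` (exact).
#' @seealso [format_coverage()] for the display convention.
#' @export
coverage_percent <- function(n_examples, space) {
  stopifnot(space >= 1)
  100 * n_examples / space
}

#' Display a coverage percentage
#'
#' Values of at least 0.1% are shown with two decimals; smaller values are
#' truncated to two significant digits (e.g. 0.015625 displays as `0.015`).
#'
#' @param x Coverage percentage from [coverage_percent()].
#' @return Character scalar (without the `%` sign).
#' @export
format_coverage <- function(x) {
  stopifnot(length(x) == 1, x >= 0)
  if (x == 0) return("0")
  if (x >= 0.1) {
    return(format(round(x, 2), scientific = FALSE, trim = TRUE))
  }
  e <- floor(log10(x))
  y <- floor(x / 10^(e - 1)) * 10^(e - 1)
  format(y, scientific = FALSE, trim = TRUE)
}

## Unrank the r-th (0-based) k-combination of {1..n} in lexicographic order.
unrank_combination <- function(r, n, k) {
  out <- integer(k)
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Enumerate assignments of an exact-order slice of the search space
#'
#' Deterministic lexicographic order: position subsets are enumerated in
#' lexicographic order of their hotspot indices, and within a subset the
#' target letters run through the alphabet with the last chosen position
#' varying fastest.  Supplying `indices` enumerates an arbitrary slice, which
#' allows streaming through spaces too large to hold in memory.
#'
#' @inheritParams parse_variant_name
#' @param l_exact Number of positions chosen per assignment.
#' @param indices 1-based global indices into the space (default: all).
#' @return Integer assignment matrix (length(indices) x n_hotspots).
#' @export
enumerate_assignments <- function(hotspots, l_exact, indices = NULL) {
  n_hot <- length(hotspots)
  aa <- length(hotspots$alphabet)
  if (l_exact < 1 || l_exact > n_hot) {
    abort("`l_exact` must satisfy 1 <= l_exact <= n_hot")
  }
  space <- search_space_size(n_hot, l_exact, aa)
  if (is.null(indices)) indices <- seq_len(space)
  if (any(indices < 1 | indices > space)) abort("indices out of range")
  m <- length(indices)
  out <- matrix(0L, nrow = m, ncol = n_hot)
  aal <- as.numeric(aa)^l_exact
  r0 <- indices - 1
  sub_rank <- floor(r0 / aal)
  let_rank <- r0 - sub_rank * aal
  prev_rank <- -1
  subset <- NULL
  for (i in seq_len(m)) {
    if (sub_rank[i] != prev_rank) {
      subset <- unrank_combination(sub_rank[i], n_hot, l_exact)
      prev_rank <- sub_rank[i]
    }
    r <- let_rank[i]
    for (j in rev(seq_len(l_exact))) {
      out[i, subset[j]] <- as.integer(r %% aa) + 1L
      r <- floor(r / aa)
    }
  }
  out
}

#' Enumerate every variant of an exact-order combinatorial library
#'
#' @inheritParams enumerate_assignments
#' @param max_size Refuse to materialize spaces larger than this (streaming
#'   via [enumerate_assignments()] is the intended route for such spaces).
#' @return A tibble with column `variant_name` in deterministic
#'   lexicographic order; the assignment matrix is attached as attribute
#'   `"assignments"`.
#' @examples
#' hs <- hotspot_set(c(19, 57), c("F", "W"), alphabet = c("A", "C", "D"))
#' enumerate_library(hs, 2)
#' @export
enumerate_library <- function(hotspots, l_exact, max_size = 1e6) {
  space <- search_space_size(length(hotspots), l_exact, length(hotspots$alphabet))
  if (space > max_size) {
    abort(paste0("space of ", format(space, scientific = FALSE),
                 " variants exceeds max_size; use enumerate_assignments() in chunks"))
  }
  assignments <- enumerate_assignments(hotspots, l_exact)
  out <- tibble::tibble(variant_name = format_variants(assignments, hotspots))
  attr(out, "assignments") <- assignments
  out
}

## One batch of hierarchical-uniform draws: order L ~ U{1..l_max}, then a
## uniform position subset without replacement, then i.i.d. uniform letters.
draw_assignments <- function(hotspots, l_max, m) {
  n_hot <- length(hotspots)
  aa <- length(hotspots$alphabet)
  out <- matrix(0L, nrow = m, ncol = n_hot)
  Ls <- sample.int(l_max, m, replace = TRUE)
  for (i in seq_len(m)) {
    pos <- sample.int(n_hot, Ls[i])
    out[i, pos] <- sample.int(aa, Ls[i], replace = TRUE)
  }
  out
}

#' Randomly sample a combinatorial mutant library
#'
#' Draws variants by the hierarchical-uniform law (mutant order uniform on
#' `{1..l_max}`, then positions uniform without replacement, then target
#' letters uniform over the alphabet), rejecting duplicates so the library
#' contains `n` distinct variants.  When `n` equals the full space size the
#' exhaustive order-`l_max` enumeration is returned instead.
#'
#' @inheritParams parse_variant_name
#' @param l_max Maximum mutant order.
#' @param n Number of distinct variants to draw.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble with column `variant_name`; assignment matrix attached as
#'   attribute `"assignments"`; attribute `"provenance"` records the draw.
#' @examples
#' hs <- demo_hotspots()
#' lib <- sample_library(hs, l_max = 4, n = 100, seed = 1)
#' @export
sample_library <- function(hotspots, l_max, n, seed) {
  n_hot <- length(hotspots)
  aa <- length(hotspots$alphabet)
  space <- search_space_size(n_hot, l_max, aa)
  if (n > space) abort("`n` exceeds the size of the combinatorial space")
  if (n == space) {
    out <- enumerate_library(hotspots, l_max, max_size = space)
    attr(out, "provenance") <- sprintf("exhaustive enumeration (l_max=%d)", l_max)
    return(out)
  }
  with_local_seed(seed, {
    seen <- character(0)
    rows <- vector("list", 0)
    guard <- 0L
    while (length(seen) < n) {
      guard <- guard + 1L
      if (guard > 1000L) abort("sampling failed to reach n distinct variants")
      batch <- draw_assignments(hotspots, l_max, max(2L * (n - length(seen)), 64L))
      nm <- format_variants(batch, hotspots)
      keep <- !duplicated(nm) & !(nm %in% seen)
      if (!any(keep)) next
      batch <- batch[keep, , drop = FALSE]
      nm <- nm[keep]
      take <- seq_len(min(nrow(batch), n - length(seen)))
      rows[[length(rows) + 1L]] <- batch[take, , drop = FALSE]
      seen <- c(seen, nm[take])
    }
    assignments <- do.call(rbind, rows)
    out <- tibble::tibble(variant_name = seen)
    attr(out, "assignments") <- assignments
    attr(out, "provenance") <- sprintf(
      "hierarchical-uniform sample: n=%d, l_max=%d, seed=%d", n, l_max, seed)
    out
  })
}

#' Split a dataset into train / validation / test index sets
#'
#' @param n Number of examples.
#' @param fractions Numeric triple summing to 1 (default `c(0.8, 0.1, 0.1)`;
#'   use `c(0.8, 0.2, 0)` for an 80:20 train/validation split).
#' @param seed Integer seed for the shuffle.
#' @return A list of disjoint, exhaustive integer index vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three non-negative numbers summing to 1")
  }
  sizes <- round(fractions * n)
  sizes[which.max(fractions)] <- sizes[which.max(fractions)] + (n - sum(sizes))
  if (any(sizes < 0)) abort("rounded split sizes are inconsistent")
  perm <- with_local_seed(seed, sample.int(n))
  list(
    train      = sort(perm[seq_len(sizes[1])]),
    validation = sort(perm[seq_len(sizes[2]) + sizes[1]]),
    test       = sort(perm[seq_len(sizes[3]) + sizes[1] + sizes[2]])
  )
}

#' Whiten labels to zero mean and unit standard deviation
#'
#' @param y Numeric vector of raw labels (length >= 2, non-constant).
#' @return A list with `values` (whitened vector) and `params` (list with
#'   `mean` and `stdev`), invertible by [unwhiten_labels()].
#' @examples
#' w <- whiten_labels(c(-10, -12, -14))
#' unwhiten_labels(w$values, w$params)
#' @export
whiten_labels <- function(y) {
  if (length(y) < 2) abort("need at least two labels to whiten")
  m <- mean(y)
  s <- sd(y)
  if (!is.finite(s) || s <= 0) abort("labels are constant; standard deviation is zero")
  list(values = (y - m) / s, params = list(mean = m, stdev = s))
}

#' @rdname whiten_labels
#' @param params Whitening parameters as returned by [whiten_labels()].
#' @export
unwhiten_labels <- function(y, params) {
  y * params$stdev + params$mean
}
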