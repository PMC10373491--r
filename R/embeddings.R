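## Per-sequence embedding matrices.  A pretrained protein language model
## maps a sequence of length L to an [L x D] real matrix; the synthetic
## provider below emulates that interface deterministically so the fusion
## head can be developed and tested without pretrained weights.  Real,
## precomputed embeddings can be supplied through the file-backed provider.

#' Deterministic synthetic sequence embeddings
#'
#' Each position's row is a seeded pseudo-random vector that depends only on
#' `(position, letter, seed)`, so identical sequences always map to
#' identical matrices and two sequences differing at one position differ in
#' exactly that row.  With `leak > 0` and a landscape supplied, the first
#' coordinate of each hotspot row encodes `leak * additive_effect(position,
#' letter)`, injecting a known, learnable signal for validation studies.
#'
#' @param sequence Amino-acid sequence (character scalar).
#' @param dim Embedding dimension (>= 8; the emulated language-model width).
#' @param seed Integer seed identifying the provider.
#' @param leak Signal-injection strength in `[0, 1]` (0 = pure noise).
#' @param params Optional [generate_landscape()] supplying the additive
#'   effects for the leak.
#' @param hotspots [hotspot_set()], required when `leak > 0`.
#' @return Numeric matrix `[nchar(sequence) x dim]`.
#' @export
synthetic_embeddings <- function(sequence, dim, seed, leak = 0,
                                 params = NULL, hotspots = NULL) {
  stopifnot(dim >= 8, leak >= 0, leak <= 1)
  letters_seq <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters_seq)
  out <- matrix(0, n, dim)
  for (p in seq_len(n)) {
    key <- paste0("emb:", p, ":", letters_seq[p])
    out[p, ] <- with_local_seed(hash_seed(key, seed), rnorm(dim))
  }
  if (leak > 0) {
    if (is.null(params) || is.null(hotspots)) {
      abort("`params` and `hotspots` are required when leak > 0")
    }
    pos_tbl <- hotspots$positions
    for (j in seq_len(nrow(pos_tbl))) {
      p <- pos_tbl$position[j]
      if (p > n) next
      out[p, 1] <- leak * params$additive[j, letters_seq[p]]
    }
  }
  out
}

#' Embedding providers for the fusion model
#'
#' A provider is a function `variant_name -> [L x D] matrix`.  The synthetic
#' provider generates matrices with [synthetic_embeddings()]; the archive
#' provider looks up precomputed matrices (e.g. real language-model
#' embeddings) stored in an embedding archive written by
#' [write_embedding_archive()].
#'
#' @param hotspots A [hotspot_set()] with a reference sequence.
#' @param dim Embedding dimension.
#' @param seed Provider seed.
#' @param leak,params See [synthetic_embeddings()].
#' @return A function mapping a variant name to an embedding matrix, with
#'   attributes `embed_dim` and `embed_len`.
#' @export
embedding_provider_synthetic <- function(hotspots, dim, seed, leak = 0,
                                         params = NULL) {
  reference <- hotspots$reference_sequence
  if (is.null(reference)) abort("hotspot set lacks a reference sequence")
  f <- function(variant_name) {
    seqs <- variant_sequences(variant_name, hotspots, reference)
    synthetic_embeddings(seqs[[1]], dim, seed, leak, params, hotspots)
  }
  attr(f, "embed_dim") <- dim
  attr(f, "embed_len") <- nchar(reference)
  attr(f, "provenance") <- sprintf("synthetic(seed=%d, leak=%g)", seed, leak)
  f
}

#' @rdname embedding_provider_synthetic
#' @param path Embedding archive path (`.rds` file with a JSON manifest
#'   sidecar) as written by [write_embedding_archive()].
#' @export
embedding_provider_archive <- function(path) {
  archive <- readRDS(path)
  stopifnot(is.list(archive$matrices))
  f <- function(variant_name) {
    m <- archive$matrices[[variant_name]]
    if (is.null(m)) abort(paste0("no embedding stored for variant ", variant_name))
    m
  }
  attr(f, "embed_dim") <- archive$dim
  attr(f, "embed_len") <- archive$seq_len
  attr(f, "provenance") <- archive$provenance %||% "archive"
  f
}

#' Write an embedding archive
#'
#' Stores per-variant embedding matrices keyed by canonical name, plus a
#' JSON manifest (`<path>.json`) recording dimensions and provenance.
#'
#' @param matrices Named list of `[L x D]` matrices.
#' @param path Output path (`.rds`).
#' @param provenance Free-text description of the embedding source.
#' @return `path`, invisibly.
#' @export
write_embedding_archive <- function(matrices, path, provenance = "unknown") {
  stopifnot(length(matrices) > 0, !is.null(names(matrices)))
  d <- dim(matrices[[1]])
  saveRDS(list(matrices = matrices, seq_len = d[1], dim = d[2],
               provenance = provenance), path)
  jsonlite::write_json(
    list(n_variants = length(matrices), seq_len = d[1], dim = d[2],
         provenance = provenance),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
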