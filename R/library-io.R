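#' Read or write a mutant library as delimited text
#'
#' Library files are TSV (or CSV, by file extension) with a required header
#' and columns `variant_name` plus an optional `energy` column holding the
#' raw binding energies (kcal/mol-like; more negative = better binding).
#' The wild-type sentinel is `"WT"`.
#'
#' @param path File path (`.csv` selects comma-delimited, otherwise tabs).
#' @return A tibble with `variant_name` and, when present, `energy`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) abort(paste0("library file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"variant_name" %in% names(tbl)) {
    abort("library file must have a 'variant_name' column (header required)")
  }
  if ("energy" %in% names(tbl)) tbl$energy <- as.numeric(tbl$energy)
  if (anyDuplicated(tbl$variant_name)) {
    abort("library contains duplicate variant names")
  }
  tibble::as_tibble(tbl)
}

#' @rdname read_library
#' @param library Tibble with `variant_name` and optionally `energy`.
#' @export
write_library <- function(library, path) {
  stopifnot("variant_name" %in% names(library))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  keep <- intersect(c("variant_name", "energy"), names(library))
  readr::write_delim(library[, keep, drop = FALSE], path, delim = delim)
  invisible(path)
}

#' Build full-length mutant sequences from variant names
#'
#' Applies each variant's substitutions to the reference sequence at the
#' hotspot positions (primed-chain hotspots are applied at the same position
#' of the single reference chain, which for a homodimer carries the second
#' subunit's mutation).
#'
#' @param names Character vector of variant names.
#' @param hotspots A [hotspot_set()] whose positions all lie within the
#'   reference sequence.
#' @param reference Reference amino-acid sequence (character scalar); falls
#'   back to `hotspots$reference_sequence`.
#' @return Character vector of mutant sequences, named by variant.
#' @export
variant_sequences <- function(names, hotspots, reference = NULL) {
  reference <- reference %||% hotspots$reference_sequence
  if (is.null(reference)) abort("a reference sequence is required")
  ref <- strsplit(toupper(reference), "")[[1]]
  pos_tbl <- hotspots$positions
  if (any(pos_tbl$position > length(ref))) {
    abort("hotspot positions exceed the reference sequence length")
  }
  if (any(ref[pos_tbl$position] != pos_tbl$wt)) {
    bad <- pos_tbl$label[ref[pos_tbl$position] != pos_tbl$wt]
    abort(paste0("reference sequence disagrees with hotspot wild types at: ",
                 paste(bad, collapse = ", ")))
  }
  assignments <- parse_variants(names, hotspots)
  out <- character(length(names))
  for (i in seq_along(names)) {
    s <- ref
    hit <- which(assignments[i, ] > 0)
    if (length(hit)) {
      s[pos_tbl$position[hit]] <- hotspots$alphabet[assignments[i, hit]]
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- names
  out
}

#' Write mutant sequences to a FASTA file
#'
#' @param sequences Named character vector as from [variant_sequences()].
#' @param path Output FASTA path.
#' @export
write_variant_fasta <- function(sequences, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::AAStringSet(sequences)
    Biostrings::writeXStringSet(aa, filepath = path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(sequences)) {
      writeLines(c(paste0(">", nm), sequences[[nm]]), con)
    }
  }
  invisible(path)
}
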