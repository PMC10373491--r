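## Amino-acid property tables (AAindex-style).  A parsed table stores one
## z-scored 20-vector per selected property: raw AAindex scales differ by
## orders of magnitude, so each property is standardized to mean 0 / sd 1
## across the 20 amino acids before use as node features.

## Core eight-property subset (hydrophobicity, size, polarity, charge
## classes); the bundled file carries twelve further scales so that the
## default feature set spans the 20-letter alphabet at full rank, which the
## regressor needs to resolve arbitrary per-letter effects.
core_property_ids <- c(
  "KYTJ820101",  # hydropathy
  "GRAR740103",  # residue volume
  "GRAR740102",  # polarity
  "ZIMJ680104",  # isoelectric point
  "BHAR880101",  # flexibility
  "ZIMJ680102",  # bulkiness
  "HOPT810101",  # hydrophilicity
  "KLEP840101"   # net charge
)

parse_aaindex_flat <- function(lines) {
  entries <- list()
  descriptions <- character(0)
  i <- 1L
  cur_id <- NULL
  cur_desc <- ""
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) {
      cur_id <- trimws(sub("^H ", "", ln))
      cur_desc <- ""
    } else if (startsWith(ln, "D ") && !is.null(cur_id)) {
      cur_desc <- trimws(sub("^D ", "", ln))
    } else if (startsWith(ln, "I ") && !is.null(cur_id)) {
      vals <- character(0)
      j <- i + 1L
      while (j <= length(lines) && !startsWith(lines[j], "//") &&
             length(vals) < 20) {
        vals <- c(vals, strsplit(trimws(lines[j]), "[[:space:]]+")[[1]])
        j <- j + 1L
      }
      if (length(vals) != 20) {
        abort(paste0("property ", cur_id, ": expected 20 values, got ",
                     length(vals)))
      }
      vals[vals %in% c("NA", "-", "*")] <- NA
      v <- suppressWarnings(as.numeric(vals))
      names(v) <- AAINDEX_ORDER
      entries[[cur_id]] <- v[AA_ALPHABET]
      descriptions[cur_id] <- cur_desc
      i <- j
    }
    i <- i + 1L
  }
  list(entries = entries, descriptions = descriptions)
}

parse_property_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  idcol <- names(tbl)[1]
  missing_aa <- setdiff(AA_ALPHABET, names(tbl))
  if (length(missing_aa)) {
    abort(paste0("property table lacks amino-acid columns: ",
                 paste(missing_aa, collapse = ", ")))
  }
  entries <- list()
  for (i in seq_len(nrow(tbl))) {
    v <- as.numeric(tbl[i, AA_ALPHABET])
    names(v) <- AA_ALPHABET
    entries[[as.character(tbl[[idcol]][i])]] <- v
  }
  list(entries = entries, descriptions = setNames(rep("", length(entries)),
                                                  names(entries)))
}

#' Load an amino-acid property table
#'
#' Reads either an AAindex flat file (records introduced by `H <id>` with an
#' `I` value block) or a simple tab-delimited table (first column property
#' id, then 20 columns named by one-letter amino-acid code).  The table is
#' restricted to the requested property ids, missing values are imputed with
#' the property mean over the available letters, and each property is then
#' standardized to mean 0 / sd 1 across the 20 amino acids.
#'
#' @param path Path to the property file.  Defaults to the bundled
#'   twenty-property set: eight classic scales covering hydrophobicity,
#'   volume, polarity, isoelectric point, flexibility, bulkiness,
#'   hydrophilicity and charge, plus twelve further scales (secondary
#'   structure propensities, surface area, refractivity, mutability,
#'   polarizability and curated side-chain descriptors) chosen so that the
#'   feature vectors of the 20 amino acids have full rank.
#' @param ids Ordered character vector of property identifiers to keep
#'   (default: all properties in the file, in file order).
#' @return An object of class `aaindex_table`: list with `values` (20 x F
#'   standardized matrix, rows = amino acids in alphabetical one-letter
#'   order), `ids`, and `descriptions`.
#' @examples
#' tbl <- load_property_table()
#' colMeans(tbl$values)   # ~0 for every property
#' @export
load_property_table <- function(path = NULL, ids = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aaindex_binding.txt", package = "gcnscreen")
  }
  if (!file.exists(path)) abort(paste0("property file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  parsed <- if (startsWith(first, "H ")) {
    parse_aaindex_flat(readLines(path, warn = FALSE))
  } else {
    parse_property_tsv(path)
  }
  if (is.null(ids)) ids <- names(parsed$entries)
  unknown <- setdiff(ids, names(parsed$entries))
  if (length(unknown)) {
    abort(paste0("property id(s) not found in file: ",
                 paste(unknown, collapse = ", ")))
  }
  values <- matrix(NA_real_, nrow = 20, ncol = length(ids),
                   dimnames = list(AA_ALPHABET, ids))
  for (id in ids) {
    v <- parsed$entries[[id]]
    if (all(is.na(v))) abort(paste0("property ", id, " has no values"))
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    if (sd(v) == 0) abort(paste0("property ", id, " is constant across amino acids"))
    values[, id] <- (v - mean(v)) / sd(v)
  }
  structure(
    list(values = values, ids = ids,
         descriptions = parsed$descriptions[ids]),
    class = "aaindex_table"
  )
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat("<aaindex_table> ", length(x$ids), " standardized properties\n", sep = "")
  for (id in x$ids) cat("  ", id, " ", x$descriptions[[id]], "\n", sep = "")
  invisible(x)
}
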