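## Binding-site graph construction.  The graph has one node per selected
## residue (default N = 23).  Edges connect every node pair; edge weights are
## either the inverse Calpha-Calpha distance or all ones.  Node features are
## the standardized physicochemical property vectors of the amino acid
## occupying each residue, so the topology is constant across variants while
## the features change with the sequence.

normalize_chain_tags <- function(chain) {
  chain <- as.character(chain)
  chain[is.na(chain)] <- ""
  if (all(chain %in% c("", "'"))) return(chain)
  lv <- unique(chain)
  tags <- c("", rep("'", length(lv) - 1L))
  tags[match(chain, lv)]
}

#' Define a binding-site residue selection with coordinates
#'
#' @param position Integer residue positions (author numbering).
#' @param chain Chain labels; either tag form (`""` main chain, `"'"` primed)
#'   or letters, in which case the first distinct letter maps to the main
#'   chain and subsequent letters to the primed tag.
#' @param aa Wild-type one-letter amino acids.
#' @param coords N x 3 numeric matrix of Calpha coordinates (Angstrom).
#' @return An object of class `residue_selection`: list with a `residues`
#'   tibble (`position`, `chain`, `wt`, `label`) and the `coords` matrix.
#' @export
residue_selection <- function(position, chain, aa, coords) {
  coords <- as.matrix(coords)
  n <- length(position)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  chain <- normalize_chain_tags(rep_len(chain, n))
  aa <- toupper(aa)
  if (!all(aa %in% AA_ALPHABET)) abort("selection amino acids must be standard letters")
  key <- paste0(position, chain)
  if (anyDuplicated(key)) abort("selection (position, chain) pairs must be unique")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(
      residues = tibble::tibble(
        position = as.integer(position), chain = chain, wt = aa,
        label = paste0(aa, position, chain)
      ),
      coords = coords
    ),
    class = "residue_selection"
  )
}

#' @export
print.residue_selection <- function(x, ...) {
  cat("<residue_selection> N = ", nrow(x$residues), " residues\n", sep = "")
  cat("  ", paste(head(x$residues$label, 10), collapse = ", "),
      if (nrow(x$residues) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.residue_selection <- function(x) nrow(x$residues)

#' Read a residue selection from a plain coordinate table
#'
#' Expects tab-separated columns `position`, `chain`, `aa`, `x`, `y`, `z`
#' with a header row.
#'
#' @param path Path to the TSV file.  Defaults to the bundled synthetic
#'   23-residue binding-site fixture (synthetic coordinates; hotspot
#'   positions and wild types follow the Vf-TA binding site).
#' @return A [residue_selection()].
#' @export
read_selection_tsv <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "binding_site_synthetic.tsv",
                        package = "gcnscreen")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("position", "chain", "aa", "x", "y", "z")
  if (!all(need %in% names(tbl))) {
    abort(paste0("selection TSV must have columns: ", paste(need, collapse = ", ")))
  }
  residue_selection(tbl$position, tbl$chain, tbl$aa,
                    as.matrix(tbl[, c("x", "y", "z")]))
}

#' Read a residue selection from a PDB file
#'
#' Extracts Calpha coordinates for the requested residues of a reference
#' structure (the structure of the wild type; mutant backbone geometry is
#' never recomputed).
#'
#' @param path PDB file path.
#' @param position Residue positions to extract.
#' @param chain Chain identifiers (PDB chain letters), recycled if length 1.
#' @return A [residue_selection()].
#' @export
read_selection_pdb <- function(path, position, chain = "A") {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  chain <- rep_len(chain, length(position))
  idx <- mapply(function(p, ch) {
    hit <- which(ca$resno == p & ca$chain == ch)
    if (length(hit) == 0) {
      abort(paste0("no CA atom for residue ", p, " chain ", ch))
    }
    hit[1]
  }, position, chain)
  aa3 <- ca$resid[idx]
  aa1 <- bio3d::aa321(aa3)
  residue_selection(position, chain, aa1,
                    as.matrix(ca[idx, c("x", "y", "z")]))
}

#' Inverse-distance edge weights of a residue selection
#'
#' @param selection A [residue_selection()].
#' @return Symmetric N x N matrix with `e_ij = 1 / ||c_i - c_j||` for
#'   `i != j` and zero diagonal (units 1/Angstrom).
#' @export
edge_weights <- function(selection) {
  d <- as.matrix(stats::dist(selection$coords))
  off <- d[upper.tri(d)]
  if (any(off <= 0)) abort("coincident residue coordinates (zero distance)")
  e <- matrix(0, nrow(d), ncol(d))
  e[d > 0] <- 1 / d[d > 0]
  e
}

#' Symmetrically normalized adjacency
#'
#' Computes `A_norm = D^(-1/2) W D^(-1/2)` where `D` is the diagonal matrix
#' of row sums of the (weighted) adjacency `W`.  All eigenvalues of the
#' result lie in `[-1, 1]`.
#'
#' @param W Non-negative symmetric matrix with positive row sums.
#' @return The normalized matrix.
#' @export
normalize_adjacency <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) abort("adjacency weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-8) abort("adjacency must be symmetric")
  d <- rowSums(W)
  if (any(d <= 0)) abort("isolated node: zero row sum in adjacency")
  di <- 1 / sqrt(d)
  di * W * rep(di, each = nrow(W))
}

#' Node feature matrix for a variant
#'
#' Row i holds the standardized property vector of the amino acid occupying
#' residue i of the selection after applying the variant's substitutions.
#'
#' @param selection A [residue_selection()].
#' @param table An [load_property_table()] result.
#' @param variant Optional variant name (or `variant` assignment vector);
#'   `NULL` gives the wild-type matrix.
#' @param hotspots [hotspot_set()] required when `variant` is given.
#' @return N x F numeric matrix.
#' @export
featurize_nodes <- function(selection, table, variant = NULL, hotspots = NULL) {
  stopifnot(inherits(table, "aaindex_table"))
  occ <- selection$residues$wt
  if (!is.null(variant)) {
    if (is.null(hotspots)) abort("`hotspots` is required to interpret a variant")
    assign <- if (is.character(variant)) {
      as.integer(parse_variant_name(variant, hotspots))
    } else {
      as.integer(variant)
    }
    node_idx <- hotspot_node_index(hotspots, selection)
    hit <- which(assign > 0)
    occ[node_idx[hit]] <- hotspots$alphabet[assign[hit]]
  }
  X <- table$values[match(occ, AA_ALPHABET), , drop = FALSE]
  rownames(X) <- selection$residues$label
  X
}

#' Map hotspot positions to node indices of a selection
#'
#' @inheritParams featurize_nodes
#' @param hotspots A [hotspot_set()].
#' @return Integer vector: selection row index of each hotspot.
#' @export
hotspot_node_index <- function(hotspots, selection) {
  key_sel <- paste0(selection$residues$position, selection$residues$chain)
  key_hot <- paste0(hotspots$positions$position, hotspots$positions$chain)
  idx <- match(key_hot, key_sel)
  if (anyNA(idx)) {
    abort(paste0("hotspot(s) absent from the residue selection: ",
                 paste(hotspots$positions$label[is.na(idx)], collapse = ", ")))
  }
  wt_sel <- selection$residues$wt[idx]
  if (any(wt_sel != hotspots$positions$wt)) {
    bad <- hotspots$positions$label[wt_sel != hotspots$positions$wt]
    abort(paste0("wild-type mismatch between hotspots and selection at: ",
                 paste(bad, collapse = ", ")))
  }
  idx
}

#' Assemble the binding-site graph for a variant
#'
#' Builds node features, edge weights (constant across variants), the binary
#' adjacency and the normalized adjacency used by the graph convolution.
#' With `edge_mode = "ones"` every edge weight is set to 1 so the normalized
#' adjacency is that of the unweighted complete graph, independent of the
#' coordinates.
#'
#' @inheritParams featurize_nodes
#' @param edge_mode `"inverse_distance"` (default) or `"ones"`.
#' @return An object of class `protein_graph`: list with `X` (N x F), `E`
#'   (N x N edge weights), `A` (binary adjacency), `A_norm`, and the
#'   selection's `residues` tibble.
#' @examples
#' sel <- read_selection_tsv()
#' tbl <- load_property_table()
#' g <- build_graph(sel, tbl)
#' dim(g$X)
#' @export
build_graph <- function(selection, table, variant = NULL, hotspots = NULL,
                        edge_mode = c("inverse_distance", "ones")) {
  edge_mode <- match.arg(edge_mode)
  n <- length(selection)
  E <- if (edge_mode == "inverse_distance") {
    edge_weights(selection)
  } else {
    matrix(1, n, n) - diag(n)
  }
  A <- (E > 0) * 1
  structure(
    list(
      X = featurize_nodes(selection, table, variant, hotspots),
      E = E,
      A = A,
      A_norm = normalize_adjacency(E),
      residues = selection$residues,
      edge_mode = edge_mode
    ),
    class = "protein_graph"
  )
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("<protein_graph> N = ", nrow(x$X), " nodes, F = ", ncol(x$X),
      " features, edges = ", x$edge_mode, "\n", sep = "")
  invisible(x)
}
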