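#' Training configuration
#'
#' Defaults follow the training protocol used throughout the package: Adam
#' with learning rate 1e-4 (beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7),
#' batches of size 1, 200 epochs, and early stopping with patience 40 on
#' the validation MSE (prediction term only), restoring the best weights.
#'
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param batch_size Currently fixed at 1 (stochastic updates).
#' @param patience Early-stopping patience in epochs.
#' @param aux_loss_weight Weight of the pooling (cut + orthogonality)
#'   losses in the training objective.
#' @param weight_decay Decoupled weight decay applied to the weight
#'   matrices (not biases) at each Adam step (default 0).
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = no
#'   annealing, the default).
#' @param swa_start First epoch of stochastic weight averaging: from this
#'   epoch on, validation and the returned model use the running average
#'   of the epoch-end weights, which smooths the noisy plateau of
#'   batch-size-1 updates (0 = off, the default).
#' @param clip_norm Per-step global gradient-norm clip (default 5; 0
#'   disables).  Single-example updates occasionally produce very large
#'   gradients through the sharp pooling softmax, and an unclipped step
#'   can collapse training for unlucky seeds.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 200, learning_rate = 1e-4, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-7, batch_size = 1,
                         patience = 40, aux_loss_weight = 1.0,
                         weight_decay = 0, lr_decay = 1, swa_start = 0,
                         clip_norm = 5) {
  stopifnot(epochs >= 1, learning_rate > 0, patience >= 1,
            batch_size == 1, aux_loss_weight >= 0, weight_decay >= 0,
            lr_decay > 0, lr_decay <= 1, swa_start >= 0, clip_norm >= 0)
  patience <- min(patience, epochs)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         aux_loss_weight = aux_loss_weight, weight_decay = weight_decay,
         lr_decay = lr_decay, swa_start = as.integer(swa_start),
         clip_norm = clip_norm),
    class = "train_config"
  )
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

## assign_gain scales the initial assignment weights: a plain small-weight
## init leaves the row-softmax of the pooling layer near uniform, which is a
## saddle where clusters never differentiate and node identity is averaged
## away; a high-gain init breaks that symmetry from the start.
init_gcn_params <- function(n_features, hidden, clusters, penultimate = 8L,
                            readout_hidden = 0L, assign_gain = 15,
                            seed = 1L) {
  with_local_seed(seed, {
    p <- list(
      Wm = glorot(n_features, hidden),
      Ws = glorot(n_features, hidden),
      b1 = rep(0, hidden),
      Wp = glorot(hidden, clusters) * assign_gain,
      bp = rep(0, clusters)
    )
    if (readout_hidden > 0) {
      p$Wr0 <- glorot(clusters * hidden, readout_hidden)
      p$br0 <- rep(0, readout_hidden)
      p$Wr1 <- glorot(readout_hidden, penultimate)
    } else {
      p$Wr1 <- glorot(clusters * hidden, penultimate)
    }
    p$br1 <- rep(0, penultimate)
    p$Wr2 <- as.vector(glorot(penultimate, 1))
    p$br2 <- 0
    p
  })
}

activation_code <- function(activation) {
  match(activation, c("relu", "identity", "tanh")) - 1L
}

## Shared context: everything needed to featurize a batch of variants for
## the compiled forward pass.
gcn_context <- function(hotspots, selection, table, edge_mode) {
  graph <- build_graph(selection, table, edge_mode = edge_mode)
  list(
    hotspots = hotspots,
    selection = selection,
    table = table,
    edge_mode = edge_mode,
    At = graph$A_norm,
    X0 = featurize_nodes(selection, table),
    hot_idx = hotspot_node_index(hotspots, selection)
  )
}

#' Train the graph convolutional binding-energy regressor
#'
#' Whitens the labels, splits the library, and trains the graph model
#' (graph convolution with skip, MinCut-style pooling, dense readout) by
#' stochastic Adam with early stopping on the validation MSE.  Fully
#' reproducible for a given `seed`, which governs weight initialization,
#' the train/validation/test split and the epoch shuffles.
#'
#' @param data Tibble with columns `variant_name` and `energy` (raw
#'   energies; they are whitened internally).
#' @param hotspots A [hotspot_set()].
#' @param selection A [residue_selection()] containing all hotspots
#'   (default: the bundled 23-residue binding site).
#' @param table Property table from [load_property_table()] (default:
#'   bundled twenty-property set).
#' @param edge_mode `"inverse_distance"` (default) or `"ones"`.
#' @param hidden Width of the convolution layer (default 32).
#' @param clusters Number of pooling clusters K (default 8, must be < N).
#'   Cluster counts close to N let the pooled graph resolve individual
#'   residues, which markedly improves recovery of arbitrary per-position
#'   effects (see the methods vignette).
#' @param readout_hidden Optional extra hidden width in the readout MLP
#'   between the flattened pooled graph and the 8-unit penultimate layer
#'   (0 = direct dense-to-8, the default).
#' @param assign_gain Multiplier on the initial assignment weights of the
#'   pooling layer; values well above 1 break the uniform-softmax symmetry
#'   so that clusters differentiate (default 15).
#' @param activation Elementwise nonlinearity of the convolution layer:
#'   `"relu"` (default), `"identity"` (a linear convolution, which makes
#'   the model affine in the node features for fixed assignments — the
#'   right bias for purely additive landscapes), or `"tanh"`.
#' @param config A [train_config()].
#' @param fractions Train/validation/test split fractions.
#' @param seed Integer seed.
#' @return An object of class `gcn_fit`.
#' @examples
#' \donttest{
#' hs <- demo_hotspots(alphabet = c("A", "C", "D", "E"))
#' land <- generate_landscape(hs, epistatic_fraction = 0, sigma = 0, seed = 7)
#' lib <- make_dataset(land, hs, l_max = 2, n = 300, seed = 7)
#' fit <- gcn_train(lib, hs, config = train_config(epochs = 20), seed = 7)
#' glance(fit)
#' }
#' @export
gcn_train <- function(data, hotspots, selection = read_selection_tsv(),
                      table = load_property_table(),
                      edge_mode = c("inverse_distance", "ones"),
                      hidden = 32L, clusters = 8L, readout_hidden = 0L,
                      assign_gain = 15,
                      activation = c("relu", "identity", "tanh"),
                      config = train_config(),
                      fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  edge_mode <- match.arg(edge_mode)
  activation <- match.arg(activation)
  stopifnot(inherits(config, "train_config"),
            all(c("variant_name", "energy") %in% names(data)))
  ctx <- gcn_context(hotspots, selection, table, edge_mode)
  if (clusters >= length(selection)) abort("`clusters` must be < number of nodes")

  assignments <- attr(data, "assignments")
  if (is.null(assignments)) {
    assignments <- parse_variants(data$variant_name, hotspots)
  }
  occ <- occupant_letters(assignments, hotspots)

  w <- whiten_labels(data$energy)
  split <- split_dataset(nrow(data), fractions, seed = hash_seed("split", seed))
  if (length(split$train) == 0 || length(split$validation) == 0) {
    abort("training and validation splits must be non-empty")
  }

  params0 <- init_gcn_params(ncol(ctx$X0), hidden, clusters,
                             readout_hidden = readout_hidden,
                             assign_gain = assign_gain,
                             seed = hash_seed("init", seed))
  res <- cpp_gcn_train(
    occ, ctx$hot_idx, table$values, ctx$X0, ctx$At, w$values,
    split$train, split$validation, params0,
    config$epochs, config$learning_rate, config$beta1, config$beta2,
    config$epsilon, config$patience, config$aux_loss_weight,
    hash_seed("shuffle", seed), config$weight_decay %||% 0,
    config$lr_decay %||% 1, config$swa_start %||% 0L,
    activation_code(activation), config$clip_norm %||% 5
  )
  history <- tibble::tibble(
    epoch = seq_along(res$train_loss),
    train_loss = res$train_loss,
    val_loss = res$val_loss,
    val_r2 = res$val_r2
  )
  fit <- structure(
    list(
      params = res$params,
      context = ctx,
      whiten = w$params,
      config = config,
      hidden = as.integer(hidden),
      clusters = as.integer(clusters),
      activation = activation,
      history = history,
      best_epoch = res$best_epoch,
      epochs_run = res$epochs_run,
      split = split,
      seed = as.integer(seed),
      data = tibble::tibble(variant_name = data$variant_name,
                            energy = data$energy)
    ),
    class = "gcn_fit"
  )
  if (length(split$test) > 0) {
    pr <- predict(fit, data$variant_name[split$test], scale = "whitened")
    fit$test_metrics <- list(
      mse = mse(w$values[split$test], pr$.pred),
      r_squared = r_squared(w$values[split$test], pr$.pred)
    )
  }
  fit
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat("<gcn_fit> hidden = ", x$hidden, ", K = ", x$clusters,
      ", edges = ", x$context$edge_mode, "\n", sep = "")
  cat("  trained ", x$epochs_run, " epochs (best ", x$best_epoch, ")",
      "; val MSE = ", signif(min(x$history$val_loss, na.rm = TRUE), 4),
      "\n", sep = "")
  if (!is.null(x$test_metrics)) {
    cat("  test r2 = ", signif(x$test_metrics$r_squared, 4), "\n", sep = "")
  }
  invisible(x)
}

## Resolve newdata to an occupant-letter matrix + canonical names.
resolve_variants <- function(newdata, hotspots) {
  if (is.data.frame(newdata)) newdata <- newdata$variant_name
  if (is.character(newdata)) {
    assignments <- parse_variants(newdata, hotspots)
    names_chr <- newdata
  } else if (is.matrix(newdata)) {
    assignments <- newdata
    names_chr <- format_variants(newdata, hotspots)
  } else {
    abort("newdata must be variant names, a library tibble, or an assignment matrix")
  }
  list(occ = occupant_letters(assignments, hotspots), names = names_chr)
}

#' Predict binding energies for variants
#'
#' @param object A [gcn_train()] fit.
#' @param newdata Variant names (character), a library tibble with a
#'   `variant_name` column, or an assignment matrix.
#' @param scale `"energy"` (default; predictions un-whitened back to the
#'   raw label units) or `"whitened"`.
#' @param ... Unused.
#' @return A tibble with `variant_name` and `.pred`.
#' @export
predict.gcn_fit <- function(object, newdata, scale = c("energy", "whitened"),
                            ...) {
  scale <- match.arg(scale)
  rv <- resolve_variants(newdata, object$context$hotspots)
  res <- cpp_gcn_predict(rv$occ, object$context$hot_idx,
                         object$context$table$values, object$context$X0,
                         object$context$At, object$params,
                         activation_code(object$activation %||% "relu"))
  pred <- as.vector(res$yhat)
  if (scale == "energy") pred <- unwhiten_labels(pred, object$whiten)
  tibble::tibble(variant_name = rv$names, .pred = pred)
}

#' Penultimate 8-d representations of variants
#'
#' The hidden vector exposed for embedding fusion.
#'
#' @inheritParams predict.gcn_fit
#' @return Numeric matrix (n x 8), rownames = variant names.
#' @export
gcn_penultimate <- function(object, newdata) {
  rv <- resolve_variants(newdata, object$context$hotspots)
  res <- cpp_gcn_predict(rv$occ, object$context$hot_idx,
                         object$context$table$values, object$context$X0,
                         object$context$At, object$params,
                         activation_code(object$activation %||% "relu"))
  H <- res$h8
  rownames(H) <- rv$names
  H
}

#' Screen a combinatorial space with a trained model
#'
#' Enumerates the full order-`l_max` combinatorial space in deterministic
#' order, predicts every variant in chunks, and returns the `top_k`
#' variants by predicted energy (most negative = best; ties broken
#' lexicographically by name) together with the score histogram of the
#' whole space.
#'
#' @param object A [gcn_train()] fit.
#' @param l_max Mutant order of the screened space.
#' @param top_k Number of top variants to keep (default 10).
#' @param chunk_size Variants scored per chunk (default 5000).
#' @param bins Histogram bin count (default 50).
#' @param max_space Refuse larger spaces (default 2e6; the score vector of
#'   the whole space is held in memory for the histogram).
#' @return A tibble of class `gcn_screen` with columns `rank`,
#'   `variant_name`, `predicted_energy`; attributes `histogram` (tibble
#'   `bin_left`, `bin_right`, `count`) and `space` (total space size).
#' @export
gcn_screen <- function(object, l_max, top_k = 10, chunk_size = 5000,
                       bins = 50, max_space = 2e6) {
  hotspots <- object$context$hotspots
  space <- search_space_size(length(hotspots), l_max, length(hotspots$alphabet))
  if (space > max_space) {
    abort("space exceeds max_space; screen in slices with enumerate_assignments()")
  }
  space <- as.integer(space)
  top_k <- min(top_k, space)
  preds <- numeric(space)
  for (lo in seq(1L, space, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, space)
    assignments <- enumerate_assignments(hotspots, l_max, lo:hi)
    occ <- occupant_letters(assignments, hotspots)
    res <- cpp_gcn_predict(occ, object$context$hot_idx,
                           object$context$table$values, object$context$X0,
                           object$context$At, object$params,
                           activation_code(object$activation %||% "relu"))
    preds[lo:hi] <- unwhiten_labels(as.vector(res$yhat), object$whiten)
  }
  ## top-k with lexicographic tie-break on canonical name
  thr <- sort(preds, partial = top_k)[top_k]
  cand <- which(preds <= thr)
  cand_assign <- enumerate_assignments(hotspots, l_max, cand)
  cand_names <- format_variants(cand_assign, hotspots)
  ord <- order(preds[cand], cand_names)[seq_len(top_k)]
  out <- tibble::tibble(
    rank = seq_len(top_k),
    variant_name = cand_names[ord],
    predicted_energy = preds[cand][ord]
  )
  if (min(preds) == max(preds)) {
    brk <- c(min(preds) - 0.5, max(preds) + 0.5)
    bins <- 1L
  } else {
    brk <- seq(min(preds), max(preds), length.out = bins + 1)
  }
  counts <- tabulate(pmin(findInterval(preds, brk, rightmost.closed = TRUE),
                          bins), nbins = bins)
  attr(out, "histogram") <- tibble::tibble(
    bin_left = brk[-length(brk)], bin_right = brk[-1], count = counts
  )
  attr(out, "space") <- space
  class(out) <- c("gcn_screen", class(out))
  out
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single-file archive of the named weight arrays plus
#' the fit configuration, with a JSON sidecar manifest (`<path>.json`)
#' recording a content checksum used by the frozen-module contract.
#'
#' @param object A `gcn_fit`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_gcn()` returns the `gcn_fit`; `save_gcn()` returns `path`
#'   invisibly.
#' @export
save_gcn <- function(object, path) {
  stopifnot(inherits(object, "gcn_fit"))
  saveRDS(object, path)
  jsonlite::write_json(
    list(format_version = 1L, class = "gcn_fit",
         checksum = gcn_checksum(object),
         hidden = object$hidden, clusters = object$clusters,
         edge_mode = object$context$edge_mode, seed = object$seed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gcn
#' @export
load_gcn <- function(path) {
  readRDS(path)
}

#' Checksum of a model's trainable weights
#'
#' @param object A `gcn_fit` (or a bare parameter list).
#' @return Character hash of the weights; equality certifies that training
#'   another component did not touch them.
#' @export
gcn_checksum <- function(object) {
  params <- if (inherits(object, "gcn_fit")) object$params else object
  rlang::hash(params)
}
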