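## Embedding-fusion (LM-GCN style) model: a frozen, already-trained graph
## model supplies an 8-d penultimate vector per variant; a per-sequence
## embedding matrix is reduced to 8-d by a small 2D CNN; the concatenated
## 16-d vector passes through one dense output unit.  Fusion training
## updates only the reducer and the head.

reducer_dims <- function(seq_len, dim, pool_window) {
  pd <- function(n) ceiling(n / pool_window)
  r1 <- seq_len - 2; c1 <- dim - 2
  if (r1 < 1 || c1 < 1) abort("embedding matrix too small for a 3x3 convolution")
  p1r <- pd(r1); p1c <- pd(c1)
  r2 <- p1r - 2; c2 <- p1c - 2
  if (r2 < 1 || c2 < 1) abort("embedding matrix too small after first pooling")
  list(flat_per_channel = pd(r2) * pd(c2))
}

init_fusion_params <- function(seq_len, dim, channels = c(4L, 8L),
                               pool_window = 4L, seed = 1L) {
  dims <- reducer_dims(seq_len, dim, pool_window)
  c1 <- channels[1]; c2 <- channels[2]
  flat <- dims$flat_per_channel * c2
  with_local_seed(seed, {
    list(
      W1 = array(runif(9 * c1, -sqrt(6 / 10), sqrt(6 / 10)), c(3, 3, c1)),
      b1 = rep(0, c1),
      W2 = array(runif(9 * c1 * c2, -sqrt(6 / (9 * c1 + 9 * c2)),
                       sqrt(6 / (9 * c1 + 9 * c2))), c(3, 3, c1 * c2)),
      b2 = rep(0, c2),
      Wd = glorot(flat, 8L),
      bd = rep(0, 8L),
      Wh = as.vector(glorot(16L, 1L)),
      bh = 0
    )
  })
}

build_embedding_cube <- function(provider, names) {
  H1 <- provider(names[1])
  cube <- array(0, c(nrow(H1), ncol(H1), length(names)))
  cube[, , 1] <- H1
  if (length(names) > 1) {
    for (i in 2:length(names)) cube[, , i] <- provider(names[i])
  }
  cube
}

#' Train the embedding-fusion model on top of a frozen graph model
#'
#' Computes the frozen graph model's penultimate vectors and the embedding
#' matrix of every variant, then trains the 2D-CNN reducer and the 16-to-1
#' dense head with the same optimizer settings as [gcn_train()] (Adam,
#' batch size 1, early stopping on validation MSE).  The graph model's
#' weights are never updated; this is asserted by checksum.
#'
#' @param object A trained [gcn_train()] fit (frozen).
#' @param data Tibble with `variant_name` and `energy`; labels are whitened
#'   with the graph model's stored whitening parameters so both model paths
#'   see the same label scale.
#' @param provider Embedding provider (see
#'   [embedding_provider_synthetic()] / [embedding_provider_archive()]).
#' @param config A [train_config()].
#' @param fractions Train/validation/(test) split fractions (default
#'   80:20 train/validation).
#' @param channels Reducer channel counts for the two convolutions.
#' @param pool_type `"avg"` (default) or `"max"`.
#' @param pool_window Pooling window (default 4).
#' @param seed Integer seed.
#' @return An object of class `fusion_fit`.
#' @export
fusion_train <- function(object, data, provider, config = train_config(),
                         fractions = c(0.8, 0.2, 0), channels = c(4L, 8L),
                         pool_type = c("avg", "max"), pool_window = 4L,
                         seed = 1L) {
  stopifnot(inherits(object, "gcn_fit"),
            all(c("variant_name", "energy") %in% names(data)))
  pool_type <- match.arg(pool_type)
  checksum_before <- gcn_checksum(object)

  names_chr <- data$variant_name
  Hgcn <- gcn_penultimate(object, names_chr)
  Hcube <- build_embedding_cube(provider, names_chr)
  y <- (data$energy - object$whiten$mean) / object$whiten$stdev

  split <- split_dataset(nrow(data), fractions, seed = hash_seed("fsplit", seed))
  if (length(split$train) == 0 || length(split$validation) == 0) {
    abort("training and validation splits must be non-empty")
  }
  params0 <- init_fusion_params(dim(Hcube)[1], dim(Hcube)[2], channels,
                                pool_window, seed = hash_seed("finit", seed))
  res <- cpp_fusion_train(
    Hcube, Hgcn, y, split$train, split$validation, params0,
    config$epochs, config$learning_rate, config$beta1, config$beta2,
    config$epsilon, config$patience, hash_seed("fshuffle", seed),
    if (pool_type == "avg") 0L else 1L, as.integer(pool_window)
  )
  checksum_after <- gcn_checksum(object)
  if (!identical(checksum_before, checksum_after)) {
    abort("internal error: frozen graph-model weights changed during fusion training")
  }
  structure(
    list(
      params = res$params,
      gcn = object,
      gcn_checksum = checksum_after,
      provider = provider,
      pool_type = pool_type,
      pool_window = as.integer(pool_window),
      channels = as.integer(channels),
      config = config,
      history = tibble::tibble(
        epoch = seq_along(res$train_loss),
        train_loss = res$train_loss,
        val_loss = res$val_loss
      ),
      best_epoch = res$best_epoch,
      epochs_run = res$epochs_run,
      split = split,
      seed = as.integer(seed)
    ),
    class = "fusion_fit"
  )
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("<fusion_fit> reducer channels ", paste(x$channels, collapse = "/"),
      ", pool = ", x$pool_type, "\n", sep = "")
  cat("  trained ", x$epochs_run, " epochs (best ", x$best_epoch, ")",
      "; val MSE = ", signif(min(x$history$val_loss, na.rm = TRUE), 4),
      "\n", sep = "")
  invisible(x)
}

#' Reduce an embedding matrix to its 8-d representation
#'
#' Runs the trained 2D-CNN reducer (conv, pool, conv, pool, flatten, dense)
#' on a single embedding matrix.
#'
#' @param object A [fusion_train()] fit.
#' @param H Embedding matrix (seq_len x dim).
#' @return Numeric 8-vector.
#' @export
reduce_embedding <- function(object, H) {
  stopifnot(inherits(object, "fusion_fit"))
  reducer_dims(nrow(H), ncol(H), object$pool_window)  # validates size
  res <- cpp_fusion_forward(as.matrix(H), rep(0, 8), object$params,
                            if (object$pool_type == "avg") 0L else 1L,
                            object$pool_window)
  as.vector(res$r8)
}

#' Predict with the fused model
#'
#' Concatenates the frozen graph model's penultimate vector with the
#' reduced embedding (16-d total) and applies the dense head.
#'
#' @param object A [fusion_train()] fit.
#' @param newdata Variant names (character) or a library tibble.
#' @param scale `"energy"` (default) or `"whitened"`.
#' @param ... Unused.
#' @return A tibble with `variant_name` and `.pred`.
#' @export
predict.fusion_fit <- function(object, newdata, scale = c("energy", "whitened"),
                               ...) {
  scale <- match.arg(scale)
  if (is.data.frame(newdata)) newdata <- newdata$variant_name
  Hgcn <- gcn_penultimate(object$gcn, newdata)
  Hcube <- build_embedding_cube(object$provider, newdata)
  res <- cpp_fusion_predict(Hcube, Hgcn, object$params,
                            if (object$pool_type == "avg") 0L else 1L,
                            object$pool_window)
  pred <- as.vector(res$yhat)
  if (scale == "energy") pred <- unwhiten_labels(pred, object$gcn$whiten)
  tibble::tibble(variant_name = newdata, .pred = pred)
}

#' @rdname predict.fusion_fit
#' @param variant_name A single variant name.
#' @return `fuse_predict()` returns a single numeric prediction.
#' @export
fuse_predict <- function(object, variant_name, scale = c("energy", "whitened")) {
  stopifnot(length(variant_name) == 1)
  predict(object, variant_name, scale = match.arg(scale))$.pred
}
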