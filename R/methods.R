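#' @importFrom generics augment
#' @export
generics::augment

param_summary <- function(params, layer_names) {
  purrr::map_dfr(names(params), function(nm) {
    w <- params[[nm]]
    tibble::tibble(
      term = nm,
      layer = layer_names[[nm]] %||% NA_character_,
      n = length(w),
      mean = mean(w),
      sd = if (length(w) > 1) sd(as.vector(w)) else NA_real_,
      l2 = sqrt(sum(w^2))
    )
  })
}

gcn_layer_names <- c(
  Wm = "convolution (mixing)", Ws = "convolution (skip)",
  b1 = "convolution", Wp = "pooling assignment", bp = "pooling assignment",
  Wr1 = "readout hidden", br1 = "readout hidden",
  Wr2 = "readout output", br2 = "readout output"
)

#' Tidy a fitted graph model
#'
#' @param x A `gcn_fit`.
#' @param ... Unused.
#' @return One row per weight array: `term`, `layer`, `n`, `mean`, `sd`,
#'   `l2`.
#' @method tidy gcn_fit
#' @export
tidy.gcn_fit <- function(x, ...) {
  param_summary(x$params, as.list(gcn_layer_names))
}

#' @rdname tidy.gcn_fit
#' @method glance gcn_fit
#' @export
glance.gcn_fit <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$split$train),
    n_validation = length(x$split$validation),
    n_test = length(x$split$test),
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    train_loss = x$history$train_loss[x$epochs_run],
    val_loss = min(x$history$val_loss, na.rm = TRUE),
    val_r2 = x$history$val_r2[x$best_epoch],
    test_mse = x$test_metrics$mse %||% NA_real_,
    test_r2 = x$test_metrics$r_squared %||% NA_real_
  )
}

#' @rdname tidy.gcn_fit
#' @param data Library tibble to augment (default: the training library).
#' @method augment gcn_fit
#' @export
augment.gcn_fit <- function(x, data = NULL, ...) {
  data <- data %||% x$data
  pr <- predict(x, data$variant_name)
  out <- dplyr::left_join(data, pr, by = "variant_name")
  if ("energy" %in% names(out)) out$.resid <- out$energy - out$.pred
  out
}

#' @rdname tidy.gcn_fit
#' @method tidy fusion_fit
#' @export
tidy.fusion_fit <- function(x, ...) {
  param_summary(x$params, list(
    W1 = "reducer conv 1", b1 = "reducer conv 1",
    W2 = "reducer conv 2", b2 = "reducer conv 2",
    Wd = "reducer dense", bd = "reducer dense",
    Wh = "fusion head", bh = "fusion head"
  ))
}

#' @rdname tidy.gcn_fit
#' @method glance fusion_fit
#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$split$train),
    n_validation = length(x$split$validation),
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    train_loss = x$history$train_loss[x$epochs_run],
    val_loss = min(x$history$val_loss, na.rm = TRUE),
    gcn_checksum = x$gcn_checksum
  )
}

#' Plot training curves of a fitted model
#'
#' @param object A `gcn_fit` or `fusion_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @method autoplot gcn_fit
#' @export
autoplot.gcn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("epoch", "train_loss", "val_loss")],
                           -"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (whitened units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gcn_fit
#' @method autoplot fusion_fit
#' @export
autoplot.fusion_fit <- autoplot.gcn_fit

#' Plot the score distribution of a screened space
#'
#' @param object A [gcn_screen()] result.
#' @param ... Unused.
#' @return A ggplot histogram of predicted energies over the whole space.
#' @method autoplot gcn_screen
#' @export
autoplot.gcn_screen <- function(object, ...) {
  h <- attr(object, "histogram")
  ggplot2::ggplot(h, ggplot2::aes(xmin = .data$bin_left, xmax = .data$bin_right,
                                  ymin = 0, ymax = .data$count)) +
    ggplot2::geom_rect(fill = "grey30") +
    ggplot2::labs(x = "predicted binding energy", y = "variants") +
    ggplot2::theme_minimal()
}
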