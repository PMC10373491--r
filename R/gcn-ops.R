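## Reference R implementations of the model's building blocks.  These back
## the documented operation surface and the unit tests; the training loop
## uses the compiled implementations in src/, which are tested for exact
## agreement with these functions.

apply_activation <- function(Z, activation) {
  switch(activation,
    identity = Z,
    relu = pmax(Z, 0),
    tanh = tanh(Z),
    abort(paste0("unknown activation: ", activation))
  )
}

#' Graph convolution with skip connection
#'
#' Computes `activation(A_norm %*% X %*% theta_m + X %*% theta_s + bias)`:
#' a message-passing (mixing) term over the normalized adjacency plus a
#' skip term that preserves each node's own features.
#'
#' @param X Node feature matrix (N x F_in).
#' @param A_norm Normalized adjacency (N x N), see [normalize_adjacency()].
#' @param theta_m,theta_s Mixing and skip weight matrices (F_in x F_out).
#' @param bias Bias vector (length F_out) or 0.
#' @param activation `"relu"` (default), `"identity"` or `"tanh"`.
#' @return N x F_out matrix.
#' @export
gcs_conv <- function(X, A_norm, theta_m, theta_s, bias = 0,
                     activation = "relu") {
  X <- as.matrix(X)
  if (nrow(A_norm) != nrow(X) || ncol(A_norm) != nrow(X)) {
    abort("A_norm must be N x N for N = nrow(X)")
  }
  if (!all(dim(theta_m) == dim(theta_s)) || nrow(theta_m) != ncol(X)) {
    abort("theta_m and theta_s must both be F_in x F_out")
  }
  Z <- A_norm %*% X %*% theta_m + X %*% theta_s
  Z <- sweep(Z, 2, rep_len(bias, ncol(Z)), "+")
  apply_activation(Z, activation)
}

row_softmax <- function(M) {
  E <- exp(M - apply(M, 1, max))
  E / rowSums(E)
}

#' MinCut-style soft graph pooling
#'
#' A linear assignment layer followed by a row-wise softmax yields the soft
#' cluster assignment matrix `S` (N x K, rows sum to 1).  The pooled
#' features are `S' X`, the pooled adjacency `S' A_norm S`.  Two auxiliary
#' losses regularize the assignment: the cut loss
#' `-tr(S' A_norm S) / tr(S' D S)` (minimized when clusters align with
#' strongly connected groups) and the orthogonality loss
#' `|| S'S / ||S'S||_F - I_K / sqrt(K) ||_F` (minimized by balanced,
#' near-orthogonal assignments).
#'
#' @param X Node features after convolution (N x F).
#' @param A_norm Normalized adjacency (N x N).
#' @param W Assignment weights (F x K), K < N.
#' @param b Assignment bias (length K) or 0.
#' @return List with `X_pool` (K x F), `A_pool` (K x K), `S` (N x K),
#'   `cut_loss` and `ortho_loss`.
#' @export
mincut_pool <- function(X, A_norm, W, b = 0) {
  X <- as.matrix(X)
  K <- ncol(W)
  if (K >= nrow(X)) abort("number of clusters K must be smaller than N")
  M <- sweep(X %*% W, 2, rep_len(b, K), "+")
  S <- row_softmax(M)
  d <- rowSums(A_norm)
  a <- sum(S * (A_norm %*% S))
  bden <- sum(S * (d * S))
  G <- crossprod(S)
  g <- sqrt(sum(G^2))
  T_ <- G / g - diag(K) / sqrt(K)
  list(
    X_pool = crossprod(S, X),
    A_pool = crossprod(S, A_norm %*% S),
    S = S,
    cut_loss = -a / bden,
    ortho_loss = sqrt(sum(T_^2))
  )
}

#' Dense readout of the pooled graph
#'
#' Flattens the pooled node features (column-major), applies a dense layer
#' to the 8-unit penultimate representation (ReLU) and a final dense layer
#' with a single output unit.  The penultimate vector is exposed because the
#' embedding-fusion head concatenates it with a reduced sequence embedding.
#'
#' @param X_pool Pooled features (K x F).
#' @param Wr1 Dense weights ((K*F) x 8).
#' @param br1 Bias (length 8).
#' @param Wr2 Output weights (length 8).
#' @param br2 Output bias (scalar).
#' @return List with `yhat` (scalar) and `h` (penultimate 8-vector).
#' @export
readout <- function(X_pool, Wr1, br1, Wr2, br2) {
  f <- as.vector(X_pool)
  if (length(f) != nrow(Wr1)) abort("flattened pooled features do not match Wr1")
  h <- pmax(as.vector(crossprod(Wr1, f)) + br1, 0)
  list(yhat = sum(h * Wr2) + br2, h = h)
}

#' Regression metrics
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length, >= 2).
#' @return `mse()`: mean squared error; `r_squared()`:
#'   `1 - SS_res / SS_tot`.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 2) abort("need at least two observations")
  mean((y - yhat)^2)
}

#' @rdname mse
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 2) abort("need at least two observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("y is constant; r-squared is undefined")
  1 - sum((y - yhat)^2) / ss_tot
}
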