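test_that("graph convolution reduces to its skip and mixing parts", {
  set.seed(3)
  N <- 5; Fin <- 3; Fout <- 4
  X <- matrix(rnorm(N * Fin), N)
  An <- normalize_adjacency(random_weights(N, 3))
  Tm <- matrix(rnorm(Fin * Fout), Fin)
  Ts <- matrix(rnorm(Fin * Fout), Fin)
  b <- rnorm(Fout)

  ## zero mixing: pure skip
  out <- gcs_conv(X, An, Tm * 0, Ts, b, activation = "identity")
  expect_equal(out, sweep(X %*% Ts, 2, b, "+"), ignore_attr = TRUE)

  ## identity adjacency, zero skip, zero bias: pure mixing
  out2 <- gcs_conv(X, diag(N), Tm, Ts * 0, 0, activation = "identity")
  expect_equal(out2, X %*% Tm, ignore_attr = TRUE)

  expect_error(gcs_conv(X, An[1:4, 1:4], Tm, Ts), "N x N")
})

test_that("graph convolution is permutation equivariant", {
  set.seed(4)
  N <- 5
  X <- matrix(rnorm(N * 3), N)
  An <- normalize_adjacency(random_weights(N, 4))
  Tm <- matrix(rnorm(12), 3); Ts <- matrix(rnorm(12), 3)
  b <- rnorm(4)
  P <- diag(N)[sample(N), ]
  lhs <- gcs_conv(P %*% X, P %*% An %*% t(P), Tm, Ts, b)
  rhs <- P %*% gcs_conv(X, An, Tm, Ts, b)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("soft pooling has stochastic rows and sane auxiliary losses", {
  set.seed(5)
  N <- 8; Fin <- 4
  X <- matrix(rnorm(N * Fin), N)
  An <- normalize_adjacency(random_weights(N, 5))

  ## K = 1: S is the all-ones column; pooled features are column sums
  p1 <- mincut_pool(X, An, W = matrix(0.3, Fin, 1), b = 0)
  expect_equal(as.vector(p1$S), rep(1, N))
  expect_equal(as.vector(p1$X_pool), colSums(X))

  ## rows of S always sum to one
  for (seed in 1:5) {
    W <- with_seed_local(seed, matrix(rnorm(Fin * 3), Fin))
    p <- mincut_pool(X, An, W, b = rnorm(3))
    expect_equal(rowSums(p$S), rep(1, N), tolerance = 1e-7)
    expect_equal(dim(p$X_pool), c(3, Fin))
    expect_equal(dim(p$A_pool), c(3, 3))
  }
  expect_error(mincut_pool(X, An, matrix(1, Fin, N)), "smaller than N")
})

test_that("orthogonality loss is minimized by a hard balanced partition", {
  ## disconnected two-block graph, hard equal split
  blk <- matrix(1, 4, 4) - diag(4)
  An <- normalize_adjacency(rbind(cbind(blk, matrix(0, 4, 4)),
                                  cbind(matrix(0, 4, 4), blk)))
  S_hard <- cbind(rep(c(1, 0), each = 4), rep(c(0, 1), each = 4))
  ortho <- function(S) {
    G <- crossprod(S)
    norm(G / norm(G, "F") - diag(ncol(S)) / sqrt(ncol(S)), "F")
  }
  expect_equal(ortho(S_hard), 0, tolerance = 1e-12)
  ## any soft perturbation increases it
  for (seed in 1:5) {
    S_soft <- abs(S_hard + with_seed_local(seed, matrix(runif(16, 0, .4), 8)))
    S_soft <- S_soft / rowSums(S_soft)
    expect_gt(ortho(S_soft), 1e-3)
  }
  ## and the hard balanced split also minimizes the cut loss here (= -1)
  a <- sum(S_hard * (An %*% S_hard))
  b <- sum(S_hard * (rowSums(An) * S_hard))
  expect_equal(-a / b, -1)
})

test_that("readout exposes a linear 8-d penultimate head", {
  set.seed(6)
  K <- 3; H <- 4
  Xp <- matrix(rnorm(K * H), K)
  Wr1 <- matrix(rnorm(K * H * 8), K * H, 8)
  br1 <- rep(0, 8)
  Wr2 <- rnorm(8); br2 <- 0
  r <- readout(Xp, Wr1, br1, Wr2, br2)
  expect_length(r$h, 8)

  ## zero input, zero biases: zero output
  r0 <- readout(Xp * 0, Wr1, br1, Wr2, br2)
  expect_equal(r0$yhat, 0)

  ## doubling the final-layer weights doubles the output
  r2 <- readout(Xp, Wr1, br1, 2 * Wr2, 2 * br2)
  expect_equal(r2$yhat, 2 * r$yhat)
})

test_that("regression metrics match hand computations", {
  expect_equal(mse(c(0, 1, 2), c(0, 1, 1)), 1 / 3)
  y <- c(1, 2, 3, 4)
  expect_equal(mse(y, y), 0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_error(mse(1:3, 1:4), "equal length")
  expect_error(r_squared(rep(1, 3), 1:3), "constant")
})

test_that("compiled forward pass agrees with the R reference composition", {
  ctx <- demo_context()
  g <- build_graph(ctx$selection, ctx$table, "F85A_W57C", ctx$hotspots)
  params <- gcnscreen:::init_gcn_params(ncol(g$X), hidden = 16, clusters = 4,
                                        seed = 31)
  cpp <- gcnscreen:::cpp_gcn_forward(g$X, g$A_norm, params)

  X1 <- gcs_conv(g$X, g$A_norm, params$Wm, params$Ws, params$b1, "relu")
  pool <- mincut_pool(X1, g$A_norm, params$Wp, params$bp)
  r <- readout(pool$X_pool, params$Wr1, params$br1, params$Wr2, params$br2)

  expect_equal(cpp$yhat, r$yhat, tolerance = 1e-12)
  expect_equal(as.vector(cpp$h8), r$h, tolerance = 1e-12)
  expect_equal(cpp$S, pool$S, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cpp$Lc, pool$cut_loss, tolerance = 1e-12)
  expect_equal(cpp$Lo, pool$ortho_loss, tolerance = 1e-12)
})

test_that("alternative convolution activations agree between R and C++", {
  ctx <- demo_context()
  g <- build_graph(ctx$selection, ctx$table, "W57C", ctx$hotspots)
  params <- gcnscreen:::init_gcn_params(ncol(g$X), hidden = 8, clusters = 3,
                                        seed = 12)
  for (act in c("identity", "tanh")) {
    code <- gcnscreen:::activation_code(act)
    cpp <- gcnscreen:::cpp_gcn_forward(g$X, g$A_norm, params, code)
    X1 <- gcs_conv(g$X, g$A_norm, params$Wm, params$Ws, params$b1, act)
    pool <- mincut_pool(X1, g$A_norm, params$Wp, params$bp)
    r <- readout(pool$X_pool, params$Wr1, params$br1, params$Wr2, params$br2)
    expect_equal(cpp$yhat, r$yhat, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  N <- 6; Fin <- 3
  X <- matrix(rnorm(N * Fin), N)
  An <- normalize_adjacency(random_weights(N, 7))
  params <- gcnscreen:::init_gcn_params(Fin, hidden = 4, clusters = 2, seed = 8)
  y <- 0.4; aux <- 0.7
  g <- gcnscreen:::cpp_gcn_grads(X, An, params, y, aux)
  lossfn <- function(p) {
    f <- gcnscreen:::cpp_gcn_forward(X, An, p)
    (f$yhat - y)^2 + aux * (f$Lc + f$Lo)
  }
  eps <- 1e-6
  for (nm in names(params)) {
    pn <- params[[nm]]
    for (i in seq_along(pn)) {
      p1 <- params; p2 <- params
      p1[[nm]][i] <- pn[i] + eps
      p2[[nm]][i] <- pn[i] - eps
      num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      expect_equal(as.vector(g[[nm]])[i], num, tolerance = 1e-4)
    }
  }
})
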