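## Embedding-fusion head on a small toy problem.  Embedding matrices are
## deliberately small (seq_len 40, dim 24) so the 2D-CNN reducer stays fast.

fusion_setup <- function(seed = 5, n = 150, epi = 0.5, leak = 0,
                         gcn_epochs = 10) {
  ref <- paste(rep("GAVLISTNQD", 4), collapse = "")
  hs <- hotspot_set(position = c(5L, 12L, 23L, 31L),
                    wt = c("I", "A", "V", "G"), chain = "",
                    alphabet = c("A", "C", "D", "E", "G", "H", "I", "K"),
                    reference_sequence = ref)
  ## helix-like synthetic selection containing the hotspots
  pos <- c(2L, 5L, 8L, 12L, 15L, 19L, 23L, 26L, 28L, 31L, 35L, 38L)
  t <- seq_along(pos) * 1.7
  sel <- residue_selection(pos, "", strsplit(ref, "")[[1]][pos],
                           cbind(6 * cos(t), 6 * sin(t), 1.5 * t))
  land <- generate_landscape(hs, epi, 0, seed = seed)
  ds <- make_dataset(land, hs, l_max = 3, n = n, seed = seed)
  fit <- gcn_train(ds, hs, selection = sel, hidden = 16, clusters = 8,
                   config = train_config(epochs = gcn_epochs,
                                         learning_rate = 1e-3),
                   seed = seed)
  prov <- embedding_provider_synthetic(hs, dim = 24, seed = seed,
                                       leak = leak, params = land)
  list(hs = hs, land = land, ds = ds, fit = fit, prov = prov)
}

test_that("the reducer maps any embedding matrix to a deterministic 8-d vector", {
  s <- fusion_setup(leak = 0)
  fu <- fusion_train(s$fit, s$ds, s$prov,
                     config = train_config(epochs = 3, learning_rate = 1e-3),
                     seed = 2)
  H <- s$prov("WT")
  r <- reduce_embedding(fu, H)
  expect_length(r, 8)
  expect_identical(r, reduce_embedding(fu, H))

  ## zero input with zero biases gives the zero vector
  p0 <- fu$params
  p0$b1[] <- 0; p0$b2[] <- 0; p0$bd[] <- 0
  fu0 <- fu; fu0$params <- p0
  expect_equal(reduce_embedding(fu0, H * 0), rep(0, 8), tolerance = 1e-12)

  expect_error(reduce_embedding(fu, H[1:5, ]), "too small")
})

test_that("fusion concatenates 8+8 and the head sees both halves", {
  s <- fusion_setup(leak = 0)
  fu <- fusion_train(s$fit, s$ds, s$prov,
                     config = train_config(epochs = 3, learning_rate = 1e-3),
                     seed = 2)
  expect_length(fu$params$Wh, 16)

  nm <- s$ds$variant_name[1]
  p <- fuse_predict(fu, nm)
  expect_identical(p, fuse_predict(fu, nm))

  ## zeroing the embedding half makes the prediction depend only on the
  ## graph-model path
  fu_g <- fu
  fu_g$params$Wh[9:16] <- 0
  hgcn <- gcn_penultimate(s$fit, nm)
  expected <- sum(fu_g$params$Wh[1:8] * hgcn) + fu_g$params$bh
  got <- predict(fu_g, nm, scale = "whitened")$.pred
  expect_equal(got, unname(expected), tolerance = 1e-10)
})

test_that("fusion training leaves the graph model byte-identical", {
  s <- fusion_setup(leak = 0)
  before <- gcn_checksum(s$fit)
  params_copy <- s$fit$params
  fu <- fusion_train(s$fit, s$ds, s$prov,
                     config = train_config(epochs = 4, learning_rate = 1e-3),
                     seed = 3)
  expect_identical(gcn_checksum(s$fit), before)
  expect_identical(fu$gcn_checksum, before)
  expect_identical(s$fit$params, params_copy)
  ## while the fusion head itself did train
  expect_false(identical(fu$params$Wh, rep(0, 16)))
  expect_gte(nrow(fu$history), 4)
})

test_that("fusion analytic gradients match finite differences", {
  set.seed(9)
  H <- matrix(rnorm(18 * 16), 18, 16)
  hgcn <- rnorm(8)
  params <- gcnscreen:::init_fusion_params(18, 16, channels = c(2L, 3L),
                                           pool_window = 2L, seed = 4)
  y <- 0.3
  for (pool in c(0L, 1L)) {
    g <- gcnscreen:::cpp_fusion_grads(H, hgcn, params, y, pool, 2L)
    lossfn <- function(p) {
      f <- gcnscreen:::cpp_fusion_forward(H, hgcn, p, pool, 2L)
      (f$yhat - y)^2
    }
    eps <- 1e-6
    for (nm in names(params)) {
      pn <- params[[nm]]
      idx <- seq_along(pn)
      if (length(idx) > 40) idx <- idx[seq(1, length(idx), length.out = 40)]
      for (i in idx) {
        p1 <- params; p2 <- params
        p1[[nm]][i] <- pn[i] + eps
        p2[[nm]][i] <- pn[i] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        expect_equal(as.vector(g[[nm]])[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("fusion training is seeded and history well-formed", {
  s <- fusion_setup(leak = 0)
  fu1 <- fusion_train(s$fit, s$ds, s$prov,
                      config = train_config(epochs = 5, learning_rate = 1e-3),
                      seed = 11)
  fu2 <- fusion_train(s$fit, s$ds, s$prov,
                      config = train_config(epochs = 5, learning_rate = 1e-3),
                      seed = 11)
  expect_equal(fu1$params, fu2$params, tolerance = 0)
  expect_true(all(is.finite(fu1$history$train_loss)))
  gl <- glance(fu1)
  expect_identical(gl$gcn_checksum, gcn_checksum(s$fit))
  expect_s3_class(autoplot(fu1), "ggplot")
})

test_that("informative embeddings improve held-out accuracy, noise does not hurt", {
  ## single-seed smoke version of the multi-seed study in the acceptance
  ## suite: leaked additive signal must help on an epistatic landscape
  s <- fusion_setup(seed = 21, n = 300, epi = 0.6, leak = 1, gcn_epochs = 15)
  hold <- make_dataset(s$land, s$hs, l_max = 3, n = 150, seed = 77)
  hold <- hold[!(hold$variant_name %in% s$ds$variant_name), ]
  y <- hold$energy
  r2_gcn <- r_squared(y, predict(s$fit, hold$variant_name)$.pred)
  fu <- fusion_train(s$fit, s$ds, s$prov,
                     config = train_config(epochs = 60, learning_rate = 1e-3,
                                           patience = 60),
                     seed = 21)
  r2_fu <- r_squared(y, predict(fu, hold$variant_name)$.pred)
  expect_gt(r2_fu, r2_gcn - 0.05)
})
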