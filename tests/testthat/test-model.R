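test_that("label smoothing produces the stated target distributions", {
  expect_equal(smooth_labels(1, 2, 0.1), c(0.9, 0.1))
  expect_equal(smooth_labels(2, 5, 0.1), c(0.025, 0.9, 0.025, 0.025, 0.025))
  expect_equal(smooth_labels(3, 4, 0), c(0, 0, 1, 0))
  Y <- smooth_labels(c(1, 2, 2), 3, 0.3)
  expect_identical(dim(Y), c(3L, 3L))
  expect_equal(Y[2, ], c(0.15, 0.7, 0.15))
  for (T_ in 2:6) for (eps in c(0, 0.1, 0.5, 0.9)) {
    y <- smooth_labels(sample(T_, 1), T_, eps)
    expect_equal(sum(y), 1)
    expect_true(all(y >= 0))
  }
  expect_error(smooth_labels(1, 1, 0.1), ">= 2")
})

test_that("weighted smoothed cross-entropy matches hand evaluation", {
  probs <- rbind(c(0.9, 0.1))
  targets <- rbind(smooth_labels(1, 2, 0.1))
  hand <- -(0.9 * log(0.9) + 0.1 * log(0.1))  # ~0.3251
  expect_equal(classification_loss(probs, targets, c(1, 1)), hand)
  expect_equal(round(hand, 4), 0.3251)
  # perfect prediction with hard targets -> 0
  expect_equal(classification_loss(rbind(c(1, 0)), rbind(c(1, 0)), c(1, 1)), 0)
  # linear in the class weights
  set.seed(14)
  P <- t(apply(matrix(runif(12), 4, 3), 1, function(r) r / sum(r)))
  Y <- smooth_labels(c(1, 2, 3, 1), 3, 0.1)
  w <- c(1, 2.5, 7)
  expect_equal(classification_loss(P, Y, 2 * w),
               2 * classification_loss(P, Y, w))
})

test_that("dynamic class weights follow (1 - acc) * alpha + 1", {
  expect_equal(update_class_weights(1), 1)
  expect_equal(update_class_weights(0), 10)
  expect_equal(update_class_weights(0.5), 5.5)
  expect_equal(update_class_weights(c(0, 0.25, 1), alpha = 4), c(5, 4, 1))
  acc <- seq(0, 1, 0.05)
  w <- update_class_weights(acc)
  expect_true(all(w >= 1 & w <= 10))
  expect_true(all(diff(w) <= 0))  # higher accuracy never raises the weight
  expect_error(update_class_weights(1.2), "\\[0, 1\\]")
})

test_that("alignment loss equals the exhaustive kNN oracle", {
  set.seed(15)
  for (case in list(c(5, 5, 8), c(12, 9, 6), c(20, 20, 10))) {
    na <- case[1]; nb <- case[2]; Fd <- case[3]
    ea <- matrix(rnorm(na * 3), na, 3); eb <- matrix(rnorm(nb * 3), nb, 3)
    fa <- matrix(rnorm(na * Fd), na, Fd); fb <- matrix(rnorm(nb * Fd), nb, Fd)
    for (k in c(1, 3, min(na, nb))) for (mode in c("hard", "soft")) {
      got <- alignment_loss(ea, eb, fa, fb, k = k, mode = mode)
      expect_equal(unname(got["a"]), oracle_align_dir(ea, eb, fa, fb, k, mode),
                   tolerance = 1e-12)
      expect_equal(unname(got["b"]), oracle_align_dir(eb, ea, fb, fa, k, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("alignment loss degenerate cases behave as expected", {
  set.seed(16)
  e <- matrix(rnorm(10), 5, 2)
  f <- matrix(rnorm(20), 5, 4)
  # identical batches, K = 1: each cell predicts itself
  expect_equal(unname(alignment_loss(e, e, f, f, k = 1)), c(0, 0))
  # K = full opposite batch, hard mode: prediction is the batch feature mean
  got <- alignment_loss(e, e, f, f, k = 5, mode = "hard")
  want <- mean(rowMeans(sweep(f, 2, colMeans(f))^2))
  expect_equal(unname(got["a"]), want)
  # K beyond the opposite batch clamps with a warning
  expect_warning(alignment_loss(e, e[1:3, ], f, f[1:3, ], k = 5), "clamped")
  expect_error(alignment_loss(e, e[0, ], f, f[0, ], k = 2), "empty")
})

test_that("the composite loss adds its parts plus the L2 penalty", {
  expect_equal(total_loss(0, 0, 0, 0, numeric(3), 0.01), 0)
  expect_equal(total_loss(1, 2, 0.5, 0.25, c(10, 10), 0), 3.75)
  expect_equal(total_loss(0, 0, 0, 0, c(2), 0.01), 0.04)
  params <- list(W = matrix(1:4, 2), b = c(0.5, -0.5))
  expect_equal(total_loss(1, 1, 1, 1, params, 0.1),
               4 + 0.1 * (sum((1:4)^2) + 0.5))
})

test_that("balanced sampling equalizes expected per-type counts", {
  labels <- rep(c("big", "small"), c(900, 100))
  set.seed(17)
  counts <- replicate(200, {
    idx <- sample_batch(labels, 1000)
    sum(labels[idx] == "small")
  })
  # per-draw sd ~ sqrt(1000 * .25) = 15.8; mean of 200 draws: sd ~ 1.12
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(1000 * 0.25 / 200))
  # single type -> uniform over cells
  set.seed(18)
  idx <- sample_batch(rep("t", 50), 5000)
  expect_true(all(range(table(idx)) > 0))
  # determinism under a fixed seed
  set.seed(19); b1 <- sample_batch(labels, 100)
  set.seed(19); b2 <- sample_batch(labels, 100)
  expect_identical(b1, b2)
  expect_error(sample_batch(character(), 10), "empty")
  expect_warning(sample_batch(c("a", "b", "c"), 2), "smaller")
})

test_that("analytic gradients match finite differences", {
  cfg <- match_config(hidden_dim = 5, embed_dim = 4, epochs = 1,
                      batch_per_species = 6, k_align = 6, seed = 3)
  set.seed(30)
  n <- 6; Fd <- 7
  xa <- matrix(rnorm(n * Fd), n, Fd); xb <- matrix(rnorm(n * Fd), n, Fd)
  Ya <- smooth_labels(sample(3, n, TRUE), 3, 0.1)
  Yb <- smooth_labels(sample(2, n, TRUE), 2, 0.1)
  wa <- runif(3, 1, 10); wb <- runif(2, 1, 10)
  p <- scXmatch:::.init_params(Fd, cfg, 3, 2)
  loss_at <- function(p) {
    st <- scXmatch:::.train_step_grads(p, xa, xb, Ya, Yb, wa, wb, cfg)
    total_loss(st$cls_a, st$cls_b, st$align_a, st$align_b, p, cfg$l2_gamma)
  }
  grads <- scXmatch:::.train_step_grads(p, xa, xb, Ya, Yb, wa, wb, cfg)$grads
  h <- 1e-6
  for (nm in names(p)) {
    idx <- seq_len(min(4, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("training separates well-separated types and is reproducible", {
  sim <- simulate_species_pair(sim_config(n_types = 2, cells_per_type_a = 40,
                                          cells_per_type_b = 40,
                                          n_genes_shared = 60,
                                          n_genes_specific_a = 0,
                                          n_genes_specific_b = 0, seed = 2))
  run <- quick_fit(sim, epochs = 50, batch = 100, seed = 5)
  log <- run$fit$log
  expect_identical(nrow(log), 50L)
  expect_equal(log$acc_a[50], 1)
  expect_equal(log$acc_b[50], 1)
  expect_lt(log$loss[10], log$loss[1])  # early descent on separable data
  # second run, same seed: identical loss trajectory and weights
  run2 <- quick_fit(sim, epochs = 50, batch = 100, seed = 5)
  expect_identical(run$fit$log, run2$fit$log)
  expect_identical(run$fit$params, run2$fit$params)
  # predicted probabilities row-normalize
  pr <- predict(run$fit, run$shared$a, species = "a", type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_identical(ncol(predict(run$fit, run$shared$a, type = "embedding")),
                   32L)
})

test_that("overwhelming L2 regularization collapses the parameters", {
  sim <- simulate_species_pair(sim_config(n_types = 2, cells_per_type_a = 10,
                                          cells_per_type_b = 10,
                                          n_genes_shared = 20,
                                          n_genes_specific_a = 0,
                                          n_genes_specific_b = 0, seed = 3))
  shared <- prepare_shared_features(sim$dataset_a, sim$dataset_b, sim$graph)
  cfg <- match_config(epochs = 120, batch_per_species = 20, k_align = 5,
                      lr = 0.05, l2_gamma = 1e6, hidden_dim = 8,
                      embed_dim = 4, seed = 6)
  fit <- cellmatch(shared$a, shared$b, sim$dataset_a$cell_types,
                   sim$dataset_b$cell_types, config = cfg)
  set.seed(cfg$seed)
  init <- scXmatch:::.init_params(ncol(shared$a$values), cfg, 2, 2)
  norm_of <- function(p) sqrt(sum(unlist(p)^2))
  expect_lt(norm_of(fit$params), 0.05 * norm_of(init))
})

test_that("a non-finite loss aborts with a diagnostic", {
  sim <- simulate_species_pair(sim_config(n_types = 2, cells_per_type_a = 6,
                                          cells_per_type_b = 6,
                                          n_genes_shared = 10,
                                          n_genes_specific_a = 0,
                                          n_genes_specific_b = 0, seed = 4))
  shared <- prepare_shared_features(sim$dataset_a, sim$dataset_b, sim$graph)
  va <- shared$a$values; va[, 1] <- NaN
  expect_error(
    cellmatch(va, shared$b$values, sim$dataset_a$cell_types,
              sim$dataset_b$cell_types,
              config = match_config(epochs = 2, batch_per_species = 12,
                                    k_align = 5, seed = 1)),
    "non-finite")
})

test_that("configuration defaults carry the method's standard values", {
  cfg <- match_config()
  expect_identical(cfg$hidden_dim, 64L)
  expect_identical(cfg$embed_dim, 32L)
  expect_identical(cfg$epochs, 200L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$l2_gamma, 0.01)
  expect_equal(cfg$smoothing, 0.1)
  expect_equal(cfg$weight_alpha, 9)
  expect_identical(cfg$batch_per_species, 5000L)
  expect_identical(cfg$k_align, 20L)
  expect_error(match_config(smoothing = 1))
})
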