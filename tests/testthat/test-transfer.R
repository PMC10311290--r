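# a hand-built model whose classifiers are pure bias terms: embeddings are
# irrelevant, so transfer behaviour is fully controlled by `ba` / `bb`
bias_model <- function(bias_a = c(0, 0), bias_b = c(0, 0, 0)) {
  feats <- c("f1", "f2", "f3")
  cfg <- match_config(hidden_dim = 2, embed_dim = 2, epochs = 1,
                      batch_per_species = 4, seed = 1)
  structure(list(
    params = list(W1 = matrix(0, 3, 2), b1 = c(0, 0),
                  W2 = matrix(0, 2, 2), b2 = c(0, 0),
                  Wa = matrix(0, 2, length(bias_a)), ba = bias_a,
                  Wb = matrix(0, 2, length(bias_b)), bb = bias_b),
    config = cfg, feature_ids = feats,
    types_a = paste0("t", seq_along(bias_a)),
    types_b = paste0("u", seq_along(bias_b)),
    class_weights = list(a = rep(1, length(bias_a)),
                         b = rep(1, length(bias_b))),
    species = c(a = "A", b = "B"),
    log = data.frame(epoch = 1, loss = 0, cls_a = 0, cls_b = 0,
                     align_a = 0, align_b = 0, acc_a = 1, acc_b = 1)),
    class = "cellmatch")
}

x3 <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("c", 1:4),
                                              c("f1", "f2", "f3")))

test_that("label transfer takes the opposite classifier's argmax", {
  m <- bias_model(bias_b = log(c(0.7, 0.2, 0.1)))
  lab <- transfer_labels(m, x3, from = "a")
  expect_true(all(lab == "u1"))
  expect_equal(unname(attr(lab, "max_prob")), rep(0.7, 4))
  # exact tie -> first type deterministically
  tie <- transfer_labels(bias_model(), x3, from = "a")
  expect_true(all(tie == "u1"))
  # direction b uses classifier A
  lab_b <- transfer_labels(bias_model(bias_a = log(c(0.3, 0.7))), x3, from = "b")
  expect_true(all(lab_b == "t2"))
  # feature-order mismatch refuses to predict
  bad <- x3[, c(2, 1, 3)]
  expect_error(transfer_labels(m, bad, from = "a"), "feature ordering")
})

test_that("normalized confusion matrices count transfer fractions", {
  m <- confusion_normalized(c("s1", "s1", "s1", "s1"),
                            c("d1", "d1", "d1", "d2"),
                            types_src = c("s1", "s2"),
                            types_dst = c("d1", "d2"))
  expect_equal(m["s1", ], c(d1 = 0.75, d2 = 0.25))
  expect_equal(unname(m["s2", ]), c(0, 0))       # empty type: zero row
  expect_identical(attr(m, "empty_rows"), "s2")
  # nonempty rows sum to one
  set.seed(22)
  tru <- sample(c("a", "b", "c"), 60, TRUE)
  trf <- sample(c("x", "y"), 60, TRUE)
  m2 <- confusion_normalized(tru, trf, c("a", "b", "c"), c("x", "y"))
  expect_equal(unname(rowSums(m2)), rep(1, 3))
  # all cells of each type mapping to one type gives a 0/1 matrix
  m3 <- confusion_normalized(c("a", "b"), c("y", "x"), c("a", "b"), c("x", "y"))
  expect_equal(unname(m3), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  expect_error(confusion_normalized("zz", "x", c("a"), c("x")), "unseen")
})

test_that("combining directions averages the matrix with its transpose", {
  m_ab <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a1", "a2"),
                                                      c("b1", "b2")))
  m_ba <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("b1", "b2"),
                                                      c("a1", "a2")))
  cm <- combine_directions(m_ab, m_ba)
  # entry 1.0 one way, 0.0 reciprocal -> 0.5
  expect_equal(unname(cm), matrix(0.5, 2, 2))
  # identity both ways stays identity
  id <- diag(2); dimnames(id) <- dimnames(m_ab)
  idt <- diag(2); dimnames(idt) <- dimnames(m_ba)
  expect_equal(unname(combine_directions(id, idt)), diag(2))
  # one-sided 0.5 association halves again: 0.5 one way, 0 back -> 0.25
  one <- matrix(c(0.5, 0, 0.5, 1), 2, 2, dimnames = dimnames(m_ab))
  zero <- matrix(0, 2, 2, dimnames = dimnames(m_ba))
  expect_equal(combine_directions(one, zero)["a1", "b1"], 0.25)
  # species-swap symmetry
  set.seed(23)
  r_ab <- matrix(runif(6), 2, 3, dimnames = list(c("a1", "a2"),
                                                 c("b1", "b2", "b3")))
  r_ba <- matrix(runif(6), 3, 2, dimnames = list(c("b1", "b2", "b3"),
                                                 c("a1", "a2")))
  expect_equal(combine_directions(r_ba, r_ab),
               t(combine_directions(r_ab, r_ba)))
  expect_error(combine_directions(r_ab, r_ab), "transposes")
})

test_that("ADS averages the ground-truth diagonal of the combined matrix", {
  cm <- matrix(c(1, 0, 0,
                 0, 0.5, 0,
                 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  corr <- type_correspondence(data.frame(type_a = c("a1", "a2", "a3"),
                                         type_b = c("b1", "b2", "b3")))
  expect_equal(ads(cm, corr), 0.5)
  id <- diag(3); dimnames(id) <- dimnames(cm)
  expect_equal(ads(id, corr), 1)
  expect_equal(ads(cm * 0, corr), 0)
  expect_error(ads(cm, type_correspondence(
    data.frame(type_a = character(), type_b = character()))), "empty")
  expect_error(ads(cm, type_correspondence(
    data.frame(type_a = "zz", type_b = "b1"))), "not present")
})

test_that("recall requires strict row-and-column maxima", {
  dn <- list(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  corr <- type_correspondence(data.frame(type_a = dn[[1]], type_b = dn[[2]]))
  id <- diag(3); dimnames(id) <- dn
  expect_equal(match_recall(id, corr), 1)
  # a3's diagonal 0.4 is beaten within column b3 by a2's 0.6 -> 2/3
  cm <- matrix(c(0.9, 0.0, 0.0,
                 0.0, 0.8, 0.6,
                 0.0, 0.0, 0.4), 3, 3, byrow = TRUE, dimnames = dn)
  expect_equal(match_recall(cm, corr), 2 / 3)
  # an exact tie on the row maximum counts as failure
  tie <- matrix(c(0.5, 0.5, 0,
                  0.0, 0.7, 0,
                  0.0, 0.0, 1), 3, 3, byrow = TRUE, dimnames = dn)
  expect_equal(match_recall(tie, corr), 2 / 3)
})

test_that("ADS and recall ignore the ordering of types", {
  set.seed(24)
  cm <- matrix(runif(12), 3, 4,
               dimnames = list(paste0("a", 1:3), paste0("b", 1:4)))
  corr <- type_correspondence(data.frame(type_a = c("a2", "a3"),
                                         type_b = c("b4", "b1")))
  pr <- sample(3); pc <- sample(4)
  cm_p <- cm[pr, pc]
  expect_equal(ads(cm_p, corr), ads(cm, corr))
  expect_equal(match_recall(cm_p, corr), match_recall(cm, corr))
})

test_that("match_types assembles matrices, scores and per-cell transfers", {
  m <- bias_model(bias_a = log(c(0.6, 0.4)), bias_b = log(c(0.2, 0.5, 0.3)))
  res <- match_types(m, x3, x3, labels_a = c("t1", "t1", "t2", "t2"),
                     labels_b = c("u1", "u2", "u3", "u3"))
  expect_s3_class(res, "match_result")
  expect_identical(dim(res$combined), c(2L, 3L))
  expect_true(all(res$combined >= 0 & res$combined <= 1))
  expect_true(is.na(res$ads))
  expect_identical(res$transfers$a$transferred_type, rep("u2", 4))
  expect_identical(res$transfers$b$transferred_type, rep("t1", 4))
  expect_identical(res$transfers$a$cell_id, paste0("c", 1:4))
})

test_that("separable synthetic data transfers almost every cell correctly", {
  sim <- simulate_species_pair(sim_config(n_types = 4, cells_per_type_a = 40,
                                          cells_per_type_b = 40,
                                          n_genes_shared = 120,
                                          n_genes_specific_a = 0,
                                          n_genes_specific_b = 0,
                                          dropout = 0, type_divergence = 0.02,
                                          marker_fold = 10, seed = 1))
  run <- quick_fit(sim, epochs = 80, batch = 250, seed = 1, k_align = 20)
  res <- match_types(run$fit, run$shared$a, run$shared$b,
                     sim$dataset_a$cell_types, sim$dataset_b$cell_types,
                     sim$correspondence)
  for (tr in res$transfers)
    expect_gte(mean(tr$transferred_type == tr$true_type), 0.99)
  expect_equal(res$recall, 1)
})
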