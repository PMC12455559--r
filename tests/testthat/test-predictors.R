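# Feature construction, cross-validation, pooled prediction, metrics.

test_that("kmer_features blocks are normalized compositions", {
  seqs <- c(a = "MKVM", b = "AAAA", c = "MK")
  X <- kmer_features(seqs, k = 1:2)
  k1 <- X[, startsWith(colnames(X), "k1_")]
  k2 <- X[, startsWith(colnames(X), "k2_")]
  expect_equal(unname(rowSums(k1)), c(1, 1, 1))
  expect_equal(unname(rowSums(k2)), c(1, 1, 1))
  expect_equal(X["a", "k1_M"], 0.5)
  expect_equal(X["b", "k2_AA"], 1)
})

test_that("make_folds: determinism, partition, degenerate cases", {
  ids <- paste0("e", 1:23)
  f1 <- make_folds(ids, 5, seed = 7)
  f2 <- make_folds(ids, 5, seed = 7)
  expect_identical(f1, f2)
  expect_setequal(f1$id, ids)
  expect_identical(sort(unique(f1$fold)), 1:5)
  expect_true(all(table(f1$fold) %in% 4:5))

  f5 <- make_folds(paste0("x", 1:5), 5, seed = 1)
  expect_true(all(table(f5$fold) == 1))
  expect_error(make_folds(paste0("x", 1:3), 5), "exceeds")
})

test_that("cross-split identity diagnostic handles the degenerate case", {
  seqs <- setNames(rep("MKVLAHGE", 6), paste0("s", 1:6))
  folds <- make_folds(names(seqs), 3, seed = 1)
  d <- cross_split_identity(seqs, folds)
  expect_equal(d$max_of_max, 1)
  expect_equal(d$mean_of_means, 1)
})

test_that("auroc: closed cases, oracle agreement, tie invariant", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  set.seed(61)
  for (r in 1:25) {
    n <- sample(6:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, TRUE)  # ties likely
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    expect_equal(auroc(scores, labels), auroc_pair_oracle(scores, labels))
    expect_equal(auroc(scores, labels) + auroc(scores, 1 - labels), 1)
  }
})

test_that("pooled_cv_predict: separable data, leakage guard, fold labels", {
  set.seed(71)
  n <- 40
  labels <- setNames(rep(c(0, 1), each = n / 2), paste0("e", 1:n))
  X <- cbind(signal = as.numeric(labels) * 10 + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  rownames(X) <- names(labels)
  folds <- make_folds(names(labels), 5, seed = 1)
  pred <- pooled_cv_predict(X, labels, folds, model_ridge(0.01), seed = 1)
  expect_equal(auroc(pred$score, pred$label), 1)
  expect_setequal(pred$id, names(labels))
  expect_identical(nrow(pred), as.integer(n))

  # constant-label training folds are handled by the constant-model guard
  one_class <- setNames(rep(1, 10), paste0("o", 1:10))
  Xo <- matrix(rnorm(20), 10, dimnames = list(names(one_class), c("a", "b")))
  fo <- make_folds(names(one_class), 2, seed = 1)
  p <- pooled_cv_predict(Xo, one_class, fo, model_ridge(1))
  expect_true(all(p$score == 1))

  # relabeling folds does not change deterministic pooled predictions
  folds2 <- folds
  folds2$fold <- c(5, 1, 2, 3, 4)[folds$fold]
  pred2 <- pooled_cv_predict(X, labels, folds2, model_ridge(0.01), seed = 1)
  expect_equal(pred$score[order(pred$id)], pred2$score[order(pred2$id)],
               tolerance = 1e-8)
})

test_that("bagged-tree model learns a separable rule and is seeded", {
  set.seed(81)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(x1 = y * 2 + rnorm(n, 0, 0.1), x2 = rnorm(n))
  spec <- model_bagged_trees(ntree = 50)
  set.seed(5)
  m1 <- spec$fit(X, y)
  set.seed(5)
  m2 <- spec$fit(X, y)
  p1 <- spec$predict(m1, X)
  expect_identical(p1, spec$predict(m2, X))
  expect_equal(auroc(p1, y), 1)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("score_metrics: precision boundary and Spearman conventions", {
  m <- score_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(m$precision, 1)
  # strictly monotone prediction-activity relation -> rho = 1
  m2 <- score_metrics(c(0.1, 0.4, 0.9), c(0, 0, 1), activity = c(1, 5, 30))
  expect_equal(m2$spearman, 1)
  expect_equal(score_metrics(c(0.2, 0.5, 0.8), c(0, 1, 1),
                             activity = c(3, 2, 1))$spearman, -1)
  # no positive predictions -> precision is NA, not an error
  m3 <- score_metrics(c(0.1, 0.2), c(1, 0))
  expect_true(is.na(m3$precision))
  expect_identical(m3$n_positive_pred, 0L)
})

test_that("condition_predictor_experiment runs end to end on a small world", {
  w <- small_world(seed = 42, n = 80)
  sim <- simulate_assay(w)
  s <- summarize_enzymes(sim$assay, yields = sim$yields)
  cc <- s$conditions
  sel <- cc$substrate == "cryPow" & cc$pH == 4.5 & cc$temperature == 40
  labels <- setNames(as.integer(cc$active[sel]), cc$enzyme_id[sel])
  base_ids <- head(s$enzymes$enzyme_id[s$enzymes$active], 8)
  ex <- condition_predictor_experiment(w$sequences, labels, base_ids,
                                       seed = 1)
  expect_named(ex$auroc, c("base", "tuned", "supervised"))
  expect_true(all(ex$auroc >= 0 & ex$auroc <= 1))
  expect_setequal(ex$predictions$id, setdiff(names(labels), base_ids))
})
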