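# A linearly separable, imbalanced toy problem in the (snr_min, bmax_ms)
# plane.
toy_xy <- function(n_pos = 5, n_neg = 10, gap = 2, seed = 1) {
  set.seed(seed)
  X <- data.frame(
    snr_min = c(rnorm(n_pos, 2.5, 0.3), rnorm(n_neg, 2.5 + gap, 0.3)),
    bmax_ms = c(rnorm(n_pos, 170, 5), rnorm(n_neg, 140, 5)))
  list(X = X, y = c(rep(1L, n_pos), rep(0L, n_neg)))
}

test_that("boosting drives training error to zero on separable data", {
  d <- toy_xy()
  fit <- rusboost_fit(d$X, d$y, n_rounds = 10, seed = 3)
  pred <- rusboost_predict(fit, d$X)
  expect_equal(pred$labels, d$y)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
})

test_that("every boosting round trains on a class-balanced subsample", {
  d <- toy_xy(n_pos = 4, n_neg = 12, gap = 0.8)
  fit <- rusboost_fit(d$X, d$y, n_rounds = 12, ratio = 1, seed = 9)
  for (tab in fit$audit) {
    expect_equal(unname(tab["1"]), 4L)   # all minority kept
    expect_equal(unname(tab["0"]), 4L)   # majority undersampled to ratio 1
  }
  fit2 <- rusboost_fit(d$X, d$y, n_rounds = 6, ratio = 2, seed = 9)
  for (tab in fit2$audit) expect_equal(unname(tab["0"]), 8L)
})

test_that("fitting and prediction are deterministic under a fixed seed", {
  d <- toy_xy(gap = 0.6)
  f1 <- rusboost_fit(d$X, d$y, n_rounds = 8, seed = 11)
  f2 <- rusboost_fit(d$X, d$y, n_rounds = 8, seed = 11)
  expect_identical(f1$betas, f2$betas)
  expect_identical(rusboost_predict(f1, d$X)$scores,
                   rusboost_predict(f2, d$X)$scores)
  f3 <- rusboost_fit(d$X, d$y, n_rounds = 8, seed = 12)
  expect_false(identical(rusboost_predict(f1, d$X)$scores,
                         rusboost_predict(f3, d$X)$scores))
})

test_that("a single-round ensemble reduces to its one tree", {
  d <- toy_xy(gap = 0.6)
  fit <- rusboost_fit(d$X, d$y, n_rounds = 1, seed = 4)
  expect_length(fit$trees, 1)
  tree_lab <- as.integer(as.character(
    predict(fit$trees[[1]], d$X, type = "class")))
  expect_equal(rusboost_predict(fit, d$X)$labels, tree_lab)
})

test_that("the ensemble vote matches a hand-unrolled weighted vote", {
  d <- toy_xy(n_pos = 3, n_neg = 3, gap = 0.5, seed = 21)
  fit <- rusboost_fit(d$X, d$y, n_rounds = 2, seed = 5)
  H <- vapply(fit$trees, function(tr)
    as.integer(as.character(predict(tr, d$X, type = "class"))),
    integer(nrow(d$X)))
  manual <- as.numeric(H %*% fit$alphas) / sum(fit$alphas)
  expect_equal(rusboost_predict(fit, d$X)$scores, manual, tolerance = 1e-12)
})

test_that("input validation catches degenerate problems", {
  d <- toy_xy()
  expect_error(rusboost_fit(d$X, rep(1L, nrow(d$X)), seed = 1),
               "both classes")
  expect_error(rusboost_fit(d$X[1:3, ], d$y[1:3], seed = 1), "at least 4")
  fit <- rusboost_fit(d$X, d$y, n_rounds = 3, seed = 1)
  bad <- d$X
  names(bad) <- c("a", "b")
  expect_error(rusboost_predict(fit, bad), "feature mismatch")
})

test_that("15-fold cross-validation of 15 patients is leave-one-out", {
  d <- toy_xy(n_pos = 5, n_neg = 10, gap = 2)
  rep <- cross_validate(d$X, d$y, folds = 15, seed = 2, n_rounds = 10)
  expect_equal(sort(unique(rep$predictions$fold)), 1:15)
  expect_equal(unname(table(rep$predictions$fold)), rep(1L, 15),
               ignore_attr = TRUE)
  # wide-margin cohort: perfect out-of-fold classification
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$auc, 1)
  expect_equal(sum(rep$confusion), 15)
  expect_equal(rep$training$auc, 1)
})

test_that("cross-validation rejects folds that lose a class", {
  X <- data.frame(snr_min = rnorm(4), bmax_ms = rnorm(4))
  y <- c(1L, 0L, 0L, 0L)
  expect_error(cross_validate(X, y, folds = 4, seed = 1), "lost one class")
  expect_error(cross_validate(X, y, folds = 10, seed = 1), "exceed")
})

test_that("boosting does not underperform a single tree on separable data", {
  wins <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    X <- data.frame(snr_min = c(rnorm(6, 3.0, 0.45), rnorm(6, 4.1, 0.45)),
                    bmax_ms = c(rnorm(6, 160, 8), rnorm(6, 145, 8)))
    y <- rep(c(1L, 0L), each = 6)
    boosted <- cross_validate(X, y, folds = 12, seed = s, n_rounds = 20)$auc
    single <- cross_validate(X, y, folds = 12, seed = s, n_rounds = 1)$auc
    if (boosted >= single) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("stratified folds keep both classes when folds < n", {
  d <- toy_xy(n_pos = 6, n_neg = 12, gap = 2)
  rep <- cross_validate(d$X, d$y, folds = 3, seed = 7, n_rounds = 5)
  expect_equal(sum(rep$confusion), 18)
  expect_gt(rep$auc, 0.9)
  for (f in 1:3) {
    te <- rep$predictions$truth[rep$predictions$fold == f]
    expect_equal(sum(te == 1), 2)      # stratification balances folds
  }
})
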