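test_that("pooled t test matches the closed form", {
  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  r <- t_test_two_sample(c(1, 2, 3), c(4, 5, 6))
  # pooled SD = 1, SE = sqrt(2/3), t = -3 / sqrt(2/3)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  swapped <- t_test_two_sample(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)

  degen <- t_test_two_sample(c(2, 2), c(2, 2))
  expect_equal(degen$t, 0); expect_equal(degen$p, 1)
  expect_error(t_test_two_sample(c(1, 1), c(2, 2)), "zero variance")
  expect_error(t_test_two_sample(1, c(1, 2)), "n >= 2")
})

test_that("rank-sum test is exact for small samples", {
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)

  tied <- wilcoxon_ranksum(c(5, 5), c(5, 5))
  expect_equal(tied$p, 1)

  # agrees with stats::wilcox.test exact p on tie-free data
  set.seed(2)
  x <- rnorm(6); y <- rnorm(7) + 0.8
  expect_equal(wilcoxon_ranksum(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("large-sample rank-sum uses the tie-corrected normal form", {
  set.seed(3)
  x <- sample(1:8, 15, replace = TRUE)
  y <- sample(1:8, 12, replace = TRUE) + 1
  expect_equal(wilcoxon_ranksum(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("exact rank-sum p equals a brute-force permutation oracle", {
  oracle <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    pool <- c(x, y)
    Ufor <- function(ix) {
      r <- rank(pool)
      sum(r[ix]) - n1 * (n1 + 1) / 2
    }
    obs <- Ufor(seq_len(n1))
    all_sets <- combn(n, n1)
    Us <- apply(all_sets, 2, Ufor)
    min(1, 2 * min(mean(Us <= obs + 1e-9), mean(Us >= obs - 1e-9)))
  }
  set.seed(4)
  for (i in 1:5) {
    x <- sample(1:6, 4, replace = TRUE)   # ties likely
    y <- sample(1:6, 4, replace = TRUE)
    expect_equal(wilcoxon_ranksum(x, y)$p, oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Fisher exact test follows the hypergeometric convention", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-9)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2)), 1)  # zero margin

  # enumeration oracle: sum of table probabilities <= observed
  oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    kk <- max(0, k - n):min(k, m)
    pr <- dhyper(kk, m, n, k)
    obs <- dhyper(tab[1, 1], m, n, k)
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), oracle(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(1, -1, 1, 1), 2)), "non-negative")
})

test_that("empirical AUC counts concordant pairs with half credit for ties", {
  expect_equal(roc_auc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  # invariant under strictly monotone transforms
  expect_equal(roc_auc(exp(c(1, 2, 3)), exp(c(2, 3, 4))), 7 / 9)
  # complement identity, including ties
  set.seed(6)
  for (i in 1:5) {
    x <- sample(1:5, 6, replace = TRUE)
    y <- sample(1:5, 4, replace = TRUE)
    expect_identical(roc_auc(x, y) + roc_auc(y, x), 1)
  }
  # negative-up direction flips the comparison
  expect_equal(roc_auc(c(4, 5), c(1, 2), direction = "negative-up"), 1)
})

test_that("Kaplan-Meier reproduces the printed survival fractions", {
  ev <- generate_cohort(5, 10, seed = 1)$events
  km <- km_estimate(ev)
  expect_equal(km_surv_at(km, 12), 11 / 15, tolerance = 1e-12)
  expect_equal(km_surv_at(km, 24), 10 / 15, tolerance = 1e-12)
  expect_equal(km_surv_at(km, 5), 1)

  none <- data.frame(time_months = c(3, 8, 12), event = c(0L, 0L, 0L))
  km0 <- km_estimate(none)
  expect_true(all(km0$surv == 1))

  expect_error(km_estimate(none[0, ]), "empty")
  expect_error(km_estimate(data.frame(time_months = -1, event = 1L)),
               "positive")
})

test_that("KM equals 1 - ECDF without censoring and breaks ties events-first", {
  set.seed(7)
  times <- sample(1:10, 12, replace = TRUE)
  km <- km_estimate(data.frame(time_months = times, event = 1L))
  ec <- ecdf(times)
  for (t in c(1, 3.5, 7, 10)) {
    expect_equal(km_surv_at(km, t), 1 - ec(t), tolerance = 1e-12)
  }
  # event and censoring tied at t = 5: the event counts first
  tied <- data.frame(time_months = c(5, 5, 10), event = c(1L, 0L, 0L))
  expect_equal(km_surv_at(km_estimate(tied), 5), 2 / 3, tolerance = 1e-12)
})

test_that("group comparison reports the four variables as published", {
  set.seed(8)
  pats <- data.frame(
    patient_id = sprintf("P%02d", 1:15),
    snr_min = c(rnorm(5, 2.74, 0.9), rnorm(10, 4.07, 0.95)),
    lat_max_ms = c(rnorm(5, 0.2, 3.6), rnorm(10, 0.55, 1.5)),
    bmax_ms = c(rnorm(5, 169, 25), rnorm(10, 139, 12)),
    nmax = c(rnorm(5, 35, 15), rnorm(10, 24.8, 10)),
    group = rep(c("RIS_conv", "RIS_non_conv"), c(5, 10)))
  gs <- compare_groups(pats)
  expect_equal(nrow(gs), 4)
  expect_equal(gs$test, c("t", "t", "t", "wilcoxon"))
  expect_true(all(gs$p >= 0 & gs$p <= 1))
  expect_true(all(gs$auc >= 0 & gs$auc <= 1))

  # swapping group labels maps every AUC to its complement
  sw <- pats
  sw$group <- ifelse(pats$group == "RIS_conv", "RIS_non_conv", "RIS_conv")
  gs2 <- compare_groups(sw)
  expect_equal(gs2$auc, 1 - gs$auc, tolerance = 1e-12)

  expect_error(compare_groups(pats[pats$group == "RIS_conv", ]),
               "at least 2")
})
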