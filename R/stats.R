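# Group statistics, ROC/AUC, Kaplan-Meier --------------------------------

#' Pooled-variance two-sample t test
#'
#' Student's two-sample t with pooled variance (Welch available via
#' `pooled = FALSE`), two-tailed.  A degenerate zero-variance comparison
#' with equal means returns `t = 0, p = 1`; with unequal means it is an
#' error.
#'
#' @param x,y numeric samples (each `n >= 2`).
#' @param pooled use the pooled-variance (Student) form.
#' @return list with `t`, `df`, `p`.
#' @export
t_test_two_sample <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("zero variance with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic for `x` versus `y` with midranks for ties.  For combined
#' `n <= 20` the two-tailed p-value is exact, from full enumeration of the
#' group assignments (`p = min(1, 2 * min(P(U <= u), P(U >= u)))`);
#' otherwise the normal approximation with tie correction is used (no
#' continuity correction).
#'
#' @param x,y numeric samples.
#' @return list with `U` (for `x`) and `p`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= 20) {
    cmb <- utils::combn(n, n1)
    Usub <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Usub <= U + 1e-9), mean(Usub >= U - 1e-9)))
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 == 0) return(list(U = U, p = 1))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = p)
}

#' Fisher exact test on a 2 x 2 table
#'
#' Two-sided p summing the hypergeometric probabilities of every table (at
#' the observed margins) no more probable than the observed one; a zero
#' margin gives `p = 1`.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return two-tailed p-value.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab) || !identical(dim(tab), c(2L, 2L)))
    stop("`tab` must be a 2 x 2 matrix")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Empirical ROC area under the curve
#'
#' `AUC = (concordant pairs + 0.5 * ties) / (n_neg * n_pos)`.  `direction`
#' states whether larger scores indicate the positive (converter) class:
#' `b_max`/`N_max` are positive-up, SNR is negative-up (converters have
#' lower SNR).
#'
#' @param scores_neg,scores_pos scores of the negative / positive class.
#' @param direction `"positive-up"` or `"negative-up"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_neg, scores_pos,
                    direction = c("positive-up", "negative-up")) {
  direction <- match.arg(direction)
  if (length(scores_neg) == 0 || length(scores_pos) == 0)
    stop("both groups must be non-empty")
  if (direction == "negative-up") {
    scores_neg <- -scores_neg
    scores_pos <- -scores_pos
  }
  d <- outer(scores_pos, scores_neg, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; ties between events and censorings at the
#' same time are resolved events-first (the product-limit convention).
#'
#' @param events `data.frame` with `time_months` (> 0) and `event`
#'   (1 = converted, 0 = censored).
#' @return object of class `km_curve`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(events) {
  if (nrow(events) == 0) stop("empty event table")
  if (any(events$time_months <= 0)) stop("times must be positive")
  fit <- survival::survfit(
    survival::Surv(events$time_months, events$event) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv),
            class = "km_curve")
}

#' Survival probability at a time point
#'
#' Right-continuous step lookup of the product-limit estimate.
#'
#' @param km a [km_estimate()] result.
#' @param t time (months).
#' @return `S(t)`.
#' @export
km_surv_at <- function(km, t) {
  i <- which(km$time <= t)
  if (length(i) == 0) return(1)
  km$surv[max(i)]
}

#' Group comparison table
#'
#' For each of the four patient-level variables: per-group mean and SD,
#' the designated test (pooled t for `SNR_min`, `Lat_max` and `b_max`;
#' rank-sum for `N_max`), its two-tailed p, and the empirical AUC with the
#' documented direction (SNR negative-up, the rest positive-up).  No
#' multiple-testing correction by default (`p_adjust = "holm"` available).
#'
#' @param patients the patient analysis table (see [assemble_table()]).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return `data.frame` with one row per variable.
#' @export
compare_groups <- function(patients, p_adjust = "none") {
  conv <- patients[patients$group == "RIS_conv", ]
  nonc <- patients[patients$group == "RIS_non_conv", ]
  if (nrow(conv) < 2 || nrow(nonc) < 2)
    stop("each group needs at least 2 patients")
  spec <- list(
    snr_min    = list(test = "t", direction = "negative-up"),
    lat_max_ms = list(test = "t", direction = "positive-up"),
    bmax_ms    = list(test = "t", direction = "positive-up"),
    nmax       = list(test = "wilcoxon", direction = "positive-up"))
  rows <- lapply(names(spec), function(v) {
    xc <- conv[[v]]; xn <- nonc[[v]]
    p <- if (spec[[v]]$test == "t") t_test_two_sample(xn, xc)$p
         else wilcoxon_ranksum(xn, xc)$p
    data.frame(
      feature = v,
      mean_non_conv = mean(xn), sd_non_conv = stats::sd(xn),
      mean_conv = mean(xc), sd_conv = stats::sd(xc),
      test = spec[[v]]$test, p = p,
      auc = roc_auc(xn, xc, spec[[v]]$direction),
      direction = spec[[v]]$direction,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  out
}
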