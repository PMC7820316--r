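# RUSBoost: random-undersampling boosting with depth-limited trees -------
#
# Each boosting round trains its weak learner on a class-balanced random
# undersample of the majority class (carrying the current boosting
# weights) while the AdaBoost-style weight update runs on the full set,
# which is what makes the ensemble effective on the 1:2
# converter:non-converter imbalance at n = 15.

rpart_ctrl <- function(depth) {
  rpart::rpart.control(maxdepth = depth, minsplit = 2, minbucket = 1,
                       cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0,
                       usesurrogate = 0)
}

tree_predict01 <- function(tree, df) {
  as.integer(as.character(stats::predict(tree, df, type = "class")))
}

#' Fit a RUSBoost ensemble
#'
#' Per round: (i) the majority class is randomly undersampled (without
#' replacement, seeded) down to `ratio` times the minority count;
#' (ii) a depth-limited tree is fitted on the balanced subsample with the
#' current boosting weights; (iii) the AdaBoost.M1 weight update runs on
#' the full set with pseudo-loss `eps_t` and `beta_t = eps_t / (1 - eps_t)`.
#' Rounds with `eps_t >= 0.5` are rejected and resampled (up to 10
#' retries, after which fitting stops early with a warning); `eps_t = 0`
#' floors `beta_t` at 1e-10.
#'
#' @param X numeric matrix or data.frame of features (the study uses the
#'   two most discriminant variables, `SNR_min` and `b_max`).
#' @param y binary labels, 1 = positive (converter) class.
#' @param n_rounds boosting rounds.
#' @param tree_depth maximum tree depth of the weak learner.
#' @param ratio majority:minority size ratio after undersampling
#'   (1 = balanced).
#' @param seed integer seed.
#' @return object of class `rusboost`: trees, per-round `beta` and vote
#'   weights `alpha = log(1/beta)`, and a per-round subsample audit.
#' @export
rusboost_fit <- function(X, y, n_rounds = 30, tree_depth = 2, ratio = 1,
                         seed = NULL) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 observations")
  if (length(y) != n) stop("X and y sizes differ")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  minority <- as.integer(names(which.min(table(y))))
  idx_min <- which(y == minority)
  idx_maj <- which(y != minority)
  n_take <- max(1L, round(ratio * length(idx_min)))
  n_take <- min(n_take, length(idx_maj))
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  audit <- list()
  with_seed(seed, {
    t <- 1L
    while (t <= n_rounds) {
      fitted <- FALSE
      for (try in seq_len(10L)) {
        sub <- c(idx_min, sample(idx_maj, n_take))
        df <- data.frame(.y = factor(y[sub], levels = c(0, 1)), X[sub, , drop = FALSE])
        wsub <- w[sub] / mean(w[sub])
        tree <- rpart::rpart(.y ~ ., data = df, weights = wsub,
                             method = "class", control = rpart_ctrl(tree_depth))
        h <- tree_predict01(tree, data.frame(X))
        eps <- sum(w * (h != y)) / sum(w)
        if (eps < 0.5) { fitted <- TRUE; break }
      }
      if (!fitted) {
        warning("boosting stopped early at round ", t,
                ": pseudo-loss >= 0.5 after 10 resamples")
        break
      }
      beta <- if (eps == 0) 1e-10 else eps / (1 - eps)
      w[h == y] <- w[h == y] * beta
      w <- w / sum(w)
      trees[[t]] <- tree
      betas[t] <- beta
      audit[[t]] <- table(factor(y[sub], levels = c(0, 1)))
      t <- t + 1L
    }
  })
  if (length(trees) == 0) stop("no boosting round succeeded")
  structure(list(trees = trees, betas = betas, alphas = log(1 / betas),
                 n_rounds = length(trees), ratio = ratio,
                 tree_depth = tree_depth, feature_names = colnames(X),
                 minority = minority, seed = seed, audit = audit),
            class = "rusboost")
}

#' Predict from a RUSBoost ensemble
#'
#' Score is the normalised weighted vote
#' `sum_t alpha_t * [h_t(x) = 1] / sum_t alpha_t` in `[0, 1]`; the label
#' is positive when the score reaches 0.5.
#'
#' @param model a [rusboost_fit()] ensemble.
#' @param X feature matrix or data.frame with the training columns.
#' @return list with `labels` (0/1) and `scores`.
#' @export
rusboost_predict <- function(model, X) {
  X <- as.data.frame(X)
  if (!identical(colnames(X), model$feature_names))
    stop("feature mismatch: expected columns ",
         paste(model$feature_names, collapse = ", "))
  H <- vapply(model$trees, tree_predict01, integer(nrow(X)), df = X)
  H <- matrix(H, nrow = nrow(X))
  scores <- as.numeric(H %*% model$alphas) / sum(model$alphas)
  list(labels = as.integer(scores >= 0.5), scores = scores)
}

#' Cross-validated RUSBoost evaluation
#'
#' With `folds = n` this is leave-one-out, the study protocol for its
#' 15-patient cohort (15 folds); otherwise folds are stratified and
#' seeded.  Out-of-fold scores are pooled into a single ROC; sensitivity
#' and specificity are taken at the 0.5 vote threshold.  The full-data
#' training-set metrics are reported alongside (the published "perfect"
#' figures do not say which they are).
#'
#' @inheritParams rusboost_fit
#' @param folds number of cross-validation folds (`<= n`).
#' @return object of class `classifier_report`: `sensitivity`,
#'   `specificity`, `auc`, `confusion` (2 x 2, truth x prediction),
#'   `predictions` (per-fold out-of-fold scores), and `training` (same
#'   metrics on the training set).
#' @export
cross_validate <- function(X, y, folds = 15, seed = NULL, n_rounds = 30,
                           tree_depth = 2, ratio = 1) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (folds > n) stop("`folds` cannot exceed n")
  with_seed(seed, {
    if (folds == n) {
      fold <- seq_len(n)
    } else {
      fold <- integer(n)
      for (cls in unique(y)) {
        i <- sample(which(y == cls))
        fold[i] <- rep_len(seq_len(folds), length(i))
      }
    }
    sub_seeds <- draw_subseeds(folds + 1L)
    scores <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      if (length(unique(y[tr])) < 2)
        stop("fold ", f, " lost one class entirely in training")
      fit <- rusboost_fit(X[tr, , drop = FALSE], y[tr], n_rounds,
                          tree_depth, ratio, seed = sub_seeds[f])
      scores[te] <- rusboost_predict(fit, X[te, , drop = FALSE])$scores
    }
    labels <- as.integer(scores >= 0.5)
    full <- rusboost_fit(X, y, n_rounds, tree_depth, ratio,
                         seed = sub_seeds[folds + 1L])
    trp <- rusboost_predict(full, X)
    structure(list(
      sensitivity = mean(labels[y == 1] == 1),
      specificity = mean(labels[y == 0] == 0),
      auc = roc_auc(scores[y == 0], scores[y == 1]),
      confusion = table(truth = factor(y, levels = c(0, 1)),
                        predicted = factor(labels, levels = c(0, 1))),
      predictions = data.frame(index = seq_len(n), truth = y, fold = fold,
                               score = scores, label = labels),
      training = list(
        sensitivity = mean(trp$labels[y == 1] == 1),
        specificity = mean(trp$labels[y == 0] == 0),
        auc = roc_auc(trp$scores[y == 0], trp$scores[y == 1])),
      folds = folds
    ), class = "classifier_report")
  })
}
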