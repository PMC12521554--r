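#' Percentage-bend correlation (Wilcox)
#'
#' Robust correlation that down-weights marginal outliers. For each
#' variable, deviations from the median are winsorized at the
#' `(1 - beta_bend)` empirical quantile of absolute deviations (the bend
#' constant; 0.1 gives the 10% bend estimator), values beyond the bend are
#' clipped through the psi function, and the winsorized deviations are
#' correlated. The test statistic is `t = r * sqrt((n - 2) / (1 - r^2))`
#' referred to a t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 4), finite values.
#' @param beta_bend bend constant in (0, 0.5); default 0.1.
#' @return list of class `bend_cor`: `r`, `t`, `p`, `n`, `beta_bend`.
#' @examples
#' percentage_bend_correlation(1:10, (1:10)^2)
#' @export
percentage_bend_correlation <- function(x, y, beta_bend = 0.1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")

  pbend <- function(z) {
    w <- sort(abs(z - median(z)))
    omega <- w[floor((1 - beta_bend) * n + 0.5)]
    if (omega <= 0) stop("constant vector: zero bend scale")
    psi <- (z - median(z)) / omega
    i1 <- sum(psi < -1)
    i2 <- sum(psi > 1)
    sz <- ifelse(abs(psi) <= 1, z, 0)
    phi <- (sum(sz) + omega * (i2 - i1)) / (n - i1 - i2)
    a <- (z - phi) / omega
    pmin(pmax(a, -1), 1)
  }
  a <- pbend(x)
  b <- pbend(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  structure(list(r = r, t = tstat, p = p, n = n, beta_bend = beta_bend),
            class = "bend_cor")
}

#' @export
print.bend_cor <- function(x, ...) {
  cat(sprintf("%.0f%% bend correlation: r = %.3f, t(%d) = %.2f, p = %.4g\n",
              100 * x$beta_bend, x$r, x$n - 2, x$t, x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' ANCOVA group contrast
#'
#' Ordinary least squares of `y` on an intercept, a binary group indicator
#' and one covariate (`y = 1 + group + covariate`); returns the group
#' coefficient with its t statistic and two-sided p-value. This is the
#' model used for between-group contrasts of parameter estimates and their
#' pre/post changes with pre-treatment severity as nuisance covariate.
#'
#' @param y response vector.
#' @param group binary labels (factor, character or 0/1); the coefficient is
#'   the effect of the second level.
#' @param covariate numeric nuisance covariate.
#' @return list with `coefficient`, `t`, `p`, `df`, `levels`.
#' @export
ancova_group_effect <- function(y, group, covariate) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (!all(is.finite(covariate))) stop("covariate must be finite")
  fit <- lm(y ~ g + covariate)
  sm <- summary(fit)$coefficients
  list(coefficient = unname(sm[2, 1]), t = unname(sm[2, 3]),
       p = unname(sm[2, 4]), df = fit$df.residual, levels = levels(g))
}

#' Trapezoidal AUC-ROC from decision values
#'
#' Equivalent to the normalized Mann-Whitney statistic: each
#' (positive, negative) pair contributes 1 if the positive scores higher,
#' 0.5 on ties.
#'
#' @param scores numeric decision values.
#' @param labels binary labels (the larger level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, labels) {
  lab <- as.integer(as.factor(labels)) - 1L
  if (length(unique(lab)) != 2) stop("labels must contain two classes")
  pos <- scores[lab == 1]
  neg <- scores[lab == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Cross-validated linear classification with AUC-ROC
#'
#' 5-fold cross-validation partitioned on subjects: feature-wise
#' standardization is fit on the training folds only and applied to the
#' held-out fold, a linear max-margin classifier (SVM, cost C = 1) is
#' trained per fold, held-out decision values are pooled, and the AUC-ROC
#' is computed by the trapezoidal rule. If a fold's training set lacks a
#' class, the data are re-partitioned with a fresh seed (logged via a
#' message).
#'
#' @param features subject-by-feature numeric matrix.
#' @param labels binary labels, one per subject.
#' @param k number of folds.
#' @param seed integer seed for the fold partition.
#' @return list of class `cv_auc`: `auc`, `scores` (pooled decision
#'   values), `fold_assignments`, `labels`.
#' @export
cv_classify_auc <- function(features, labels, k = 5, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("labels must match feature rows")
  lab <- as.factor(labels)
  if (nlevels(lab) != 2) stop("labels must contain two classes")
  set.seed(seed)
  repeat {
    folds <- sample(rep(seq_len(k), length.out = n))
    ok <- all(vapply(seq_len(k), function(f) {
      nlevels(droplevels(lab[folds != f])) == 2
    }, logical(1)))
    if (ok) break
    message("single-class training fold; re-partitioning")
  }
  scores <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sdev <- apply(features[tr, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    xtr <- sweep(sweep(features[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    xte <- sweep(sweep(features[!tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    model <- e1071::svm(xtr, lab[tr], kernel = "linear", cost = 1,
                        scale = FALSE)
    pred <- stats::predict(model, xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # positive decision values favour the class named first in the column
    # label; orient all folds toward the second factor level
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    dv <- dv[, 1]
    if (first != levels(lab)[2]) dv <- -dv
    scores[!tr] <- dv
  }
  structure(list(auc = auc_trapezoid(scores, lab), scores = scores,
                 fold_assignments = folds, labels = lab),
            class = "cv_auc")
}

#' Permutation p-value for a cross-validated AUC
#'
#' Repeats the whole cross-validation `n_perm` times with the label vector
#' shuffled, and returns the plain proportion of permuted AUCs at or above
#' the observed one. Re-running the cross-validation (rather than merely
#' re-scoring the pooled decision values) matters: the pooled
#' cross-validated AUC carries a negative small-sample bias under the null,
#' and only permutations that share that bias give a calibrated test.
#' `add_one = TRUE` switches to the add-one (never-zero) variant; the plain
#' proportion is the default.
#'
#' @param features,labels,k the data and fold count passed to
#'   [cv_classify_auc()].
#' @param observed_auc the AUC of the unshuffled analysis.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed (drives both the shuffles and the permuted
#'   fold partitions).
#' @param add_one use the (b + 1) / (n_perm + 1) estimator.
#' @return list with `p_perm`, `n_perm`, `perm_aucs`.
#' @export
permutation_pvalue <- function(features, labels, observed_auc, n_perm = 100,
                               k = 5, seed = 1, add_one = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  set.seed(seed)
  shuffles <- lapply(seq_len(n_perm), function(i) sample(seq_along(labels)))
  perm_aucs <- vapply(seq_len(n_perm), function(i) {
    suppressMessages(cv_classify_auc(features, labels[shuffles[[i]]], k = k,
                                     seed = seed + i)$auc)
  }, numeric(1))
  b <- sum(perm_aucs >= observed_auc)
  p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  list(p_perm = p, n_perm = n_perm, perm_aucs = perm_aucs)
}

#' Power of a one-sample t-test (exact, noncentral t)
#'
#' `P(T' > t_crit)` with noncentrality `d * sqrt(n)` and `n - 1` degrees of
#' freedom for the one-sided test; the two-sided version sums both
#' rejection tails.
#'
#' @param effect_d standardized effect size (Cohen's d).
#' @param n sample size (>= 2).
#' @param alpha significance level in (0, 1).
#' @param tails "one" or "two".
#' @return power in `[0, 1]`.
#' @examples
#' power_one_sample_t(0.42, 37, 0.05, "one")
#' @export
power_one_sample_t <- function(effect_d, n, alpha = 0.05,
                               tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (n < 2) stop("n must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n - 1
  ncp <- effect_d * sqrt(n)
  if (tails == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp)
  } else {
    tc <- qt(1 - alpha / 2, df)
    (1 - pt(tc, df, ncp)) + pt(-tc, df, ncp)
  }
}
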