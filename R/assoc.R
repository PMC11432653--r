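# The statistical battery: 2x2 odds ratios, logistic and linear regression
# with diagnostics, rank tests, ordered-trend tests, ROC analysis and
# percentile-extreme risk comparisons. Every test returns an association
# result: estimate, 95% CI, p-value, test identity and n.

#' Construct an association result
#'
#' Uniform container for every statistical result the package reports.
#' The marginal flag follows the convention that p-values in (0.05, 0.15]
#' are marginally significant.
#'
#' @param estimate Point estimate (OR, standardized beta, rho, AUC, ...).
#' @param ci_low,ci_high 95% confidence bounds (NA when not defined).
#' @param p Two-tailed p-value.
#' @param test Test name.
#' @param n Number of observations used.
#' @param extra Optional named list of test-specific extras.
#' @return A list of class `ldlprs_assoc`.
#' @export
association_result <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                               p = NA_real_, test = "", n = NA_integer_,
                               extra = list()) {
  out <- c(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                p = p, test = test, n = n,
                marginal = is.finite(p) && p > 0.05 && p <= 0.15),
           extra)
  class(out) <- "ldlprs_assoc"
  out
}

#' @export
print.ldlprs_assoc <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4g (95%% CI %.4g-%.4g), p = %.4g, n = %s%s\n",
              x$test, x$estimate, x$ci_low, x$ci_high, x$p,
              ifelse(is.na(x$n), "?", x$n),
              if (isTRUE(x$marginal)) " [marginal]" else ""))
  invisible(x)
}

#' Flatten association results to a tidy data.frame
#'
#' @param results A named list of `ldlprs_assoc` objects.
#' @return A data.frame with one row per result.
#' @export
tidy_associations <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(name = nm, test = r$test, estimate = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               n = r$n, marginal = r$marginal, stringsAsFactors = FALSE)
  }))
}

#' Odds ratio from a 2x2 table
#'
#' `OR = ad / (bc)` with the Woolf (log-normal) 95% CI
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald z
#' p-value. If any cell is zero the Haldane-Anscombe correction (+0.5 to
#' every cell) is applied and flagged.
#'
#' @param a,b,c,d Counts: exposed cases, unexposed cases, exposed controls,
#'   unexposed controls.
#' @return An association result with extras `corrected` and `table`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("degenerate 2x2 table: a full row or column is zero")
  }
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- counts[1] * counts[4] / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  z <- log(or) / se
  association_result(
    estimate = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    test = "odds ratio (Woolf CI, Wald p)",
    n = as.integer(sum(c(a, b, c, d))),
    extra = list(corrected = corrected, table = c(a = a, b = b, c = c, d = d))
  )
}

#' Binomial logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) with
#' per-covariate odds ratios, Wald CIs and p-values, plus model-level
#' summaries: deviance, Cox-Snell R-squared and classification metrics at
#' a 0.5 probability cut. Possible separation (divergent coefficients or
#' non-convergence) is reported through the `separation` flag.
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param covariates Data frame or matrix of covariates.
#' @return A list of class `ldlprs_logit` with `coefficients` (tidy
#'   data.frame with OR scale estimates), `fit` (the glm object), `model`
#'   (deviance, null deviance, cox_snell_r2, accuracy, sensitivity,
#'   specificity, aic) and `separation`.
#' @export
logistic_fit <- function(outcome, covariates) {
  y <- as.integer(as.logical(outcome))
  X <- as.data.frame(covariates)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y[!is.na(y)])) < 2) stop("outcome must contain both classes")
  dat <- cbind(data.frame(.y = y), X)
  qrX <- qr(stats::model.matrix(~ ., data = X))
  if (qrX$rank < ncol(stats::model.matrix(~ ., data = X))) {
    warning("rank-deficient design: collinear covariate columns")
  }
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  eps <- 1e-10
  separation <- !fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
    (any(stats::fitted(fit) < eps) && any(stats::fitted(fit) > 1 - eps))
  if (separation) warning("possible separation: logistic fit may be divergent")
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  coefs <- data.frame(
    term = rownames(cf),
    beta = est, se = se,
    or = exp(est),
    or_low = exp(est - 1.96 * se),
    or_high = exp(est + 1.96 * se),
    p = cf[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  prob <- stats::fitted(fit)
  pred <- prob >= 0.5
  n <- length(y)
  model <- list(
    deviance = stats::deviance(fit),
    null_deviance = fit$null.deviance,
    df_residual = fit$df.residual,
    cox_snell_r2 = 1 - exp((stats::deviance(fit) - fit$null.deviance) / n),
    accuracy = mean(pred == (y == 1)),
    sensitivity = if (any(y == 1)) mean(pred[y == 1]) else NA_real_,
    specificity = if (any(y == 0)) mean(!pred[y == 0]) else NA_real_,
    aic = stats::AIC(fit)
  )
  structure(list(coefficients = coefs, fit = fit, model = model,
                 separation = separation, n = n),
            class = "ldlprs_logit")
}

#' @export
print.ldlprs_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d): deviance %.2f, Cox-Snell R2 %.3f, accuracy %.3f\n",
              x$n, x$model$deviance, x$model$cox_snell_r2, x$model$accuracy))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into deciles of fitted risk and compares observed
#' and expected event counts with a chi-squared statistic on `g - 2`
#' degrees of freedom. Quantile ties can collapse groups; collapsed groups
#' are merged (reducing the df) and noted.
#'
#' @param probs Fitted probabilities in (0, 1).
#' @param outcome Binary outcomes.
#' @param g Number of risk groups (default 10).
#' @return An association result (`estimate` = chi-squared statistic) with
#'   extras `df` and `groups_used`.
#' @export
hosmer_lemeshow <- function(probs, outcome, g = 10) {
  y <- as.integer(as.logical(outcome))
  stopifnot(length(probs) == length(y), length(y) >= g)
  qs <- unique(stats::quantile(probs, probs = seq(0, 1, length.out = g + 1)))
  if (length(qs) < 3) {
    # all probabilities (nearly) equal: a single group carries no information
    grp <- factor(rep(1, length(y)))
  } else {
    grp <- cut(probs, breaks = qs, include.lowest = TRUE)
  }
  gk <- nlevels(droplevels(grp))
  if (gk < g) message("Hosmer-Lemeshow: ties reduced risk groups to ", gk)
  obs1 <- tapply(y, grp, sum)
  exp1 <- tapply(probs, grp, sum)
  nk <- tapply(y, grp, length)
  keep <- !is.na(nk)
  obs1 <- obs1[keep]; exp1 <- exp1[keep]; nk <- nk[keep]
  chi2 <- sum((obs1 - exp1)^2 / (exp1 * (1 - exp1 / nk)))
  df <- max(length(nk) - 2, 1)
  association_result(
    estimate = chi2,
    p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
    test = "Hosmer-Lemeshow",
    n = length(y),
    extra = list(df = df, groups_used = length(nk))
  )
}

#' Compare nested logistic models
#'
#' Primary statistic: likelihood-ratio chi-squared on the difference in
#' residual deviance, df = difference in parameters. An F-form on the
#' residual deviance (extra-deviance F) is reported alongside, together
#' with the AUC of each model.
#'
#' @param model_small,model_large Fits from [logistic_fit()]; the small
#'   model's covariates must be a subset of the large model's, on the same
#'   observations.
#' @return An association result (`estimate` = LR chi-squared) with extras
#'   `df`, `f_stat`, `f_p`, `auc_small`, `auc_large`.
#' @export
nested_model_compare <- function(model_small, model_large) {
  fs <- model_small$fit; fl <- model_large$fit
  if (length(fs$y) != length(fl$y) || any(fs$y != fl$y)) {
    stop("models must be fitted to the same observations")
  }
  small_terms <- colnames(stats::model.matrix(fs))
  large_terms <- colnames(stats::model.matrix(fl))
  if (!all(small_terms %in% large_terms)) {
    stop("models are not nested: small model has terms absent from the large model")
  }
  lr <- stats::deviance(fs) - stats::deviance(fl)
  df <- fs$df.residual - fl$df.residual
  if (df == 0) {
    return(association_result(0, p = 1, test = "likelihood ratio (nested logistic)",
                              n = length(fl$y),
                              extra = list(df = 0L, f_stat = 0, f_p = 1,
                                           auc_small = model_auc(fs),
                                           auc_large = model_auc(fl))))
  }
  lr <- max(lr, 0)
  f_stat <- (lr / df) / (stats::deviance(fl) / fl$df.residual)
  association_result(
    estimate = lr,
    p = stats::pchisq(lr, df = df, lower.tail = FALSE),
    test = "likelihood ratio (nested logistic)",
    n = length(fl$y),
    extra = list(
      df = as.integer(df),
      f_stat = f_stat,
      f_p = stats::pf(f_stat, df, fl$df.residual, lower.tail = FALSE),
      auc_small = model_auc(fs),
      auc_large = model_auc(fl)
    )
  )
}

model_auc <- function(fit) {
  auc_mann_whitney(stats::fitted(fit), fit$y == 1)
}

# AUC via the Mann-Whitney identity, ties counted 1/2
auc_mann_whitney <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Simple linear regression with standardized coefficients
#'
#' When `standardize = TRUE` both variables are z-scored before the fit, so
#' the slope is the standardized beta (SD of y per SD of x), which in
#' simple regression equals the Pearson correlation.
#'
#' @param y Response vector.
#' @param x Predictor vector.
#' @param standardize Z-score both variables first (default TRUE).
#' @return An association result (`estimate` = slope) with extra `r2`.
#' @export
linear_fit_standardized <- function(y, x, standardize = TRUE) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || (standardize && stats::sd(y) == 0)) {
    stop("degenerate input: zero variance")
  }
  if (standardize) {
    y <- as.numeric(standardize_scores(y))
    x <- as.numeric(standardize_scores(x))
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)["x", ]
  association_result(
    estimate = cf["x", "Estimate"],
    ci_low = ci[1], ci_high = ci[2],
    p = cf["x", "Pr(>|t|)"],
    test = if (standardize) "linear regression (standardized beta)"
           else "linear regression",
    n = length(y),
    extra = list(r2 = summary(fit)$r.squared)
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with the t-approximation p-value.
#'
#' @param x,y Numeric vectors.
#' @return An association result (`estimate` = rho). The CI is a Fisher-z
#'   large-sample interval on rho.
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  # Fisher z interval with the conventional Spearman variance inflation
  zse <- sqrt(1.06 / (n - 3))
  zr <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  association_result(
    estimate = rho,
    ci_low = tanh(zr - 1.96 * zse), ci_high = tanh(zr + 1.96 * zse),
    p = ct$p.value,
    test = "Spearman correlation",
    n = n
  )
}

#' Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with `a > b` (ties counted 1/2), i.e.
#' the statistic reported by [stats::wilcox.test()] for `wilcox.test(A, B)`.
#' The p-value is exact (enumeration) when the smaller group has at most 8
#' observations and there are no ties, otherwise a tie-corrected normal
#' approximation is used.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An association result (`estimate` = U).
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- min(length(a), length(b)) <= 8 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = !exact))
  association_result(
    estimate = unname(wt$statistic),
    p = wt$p.value,
    test = paste0("Mann-Whitney U (", if (exact) "exact" else "normal approx.", ")"),
    n = length(a) + length(b)
  )
}

# JT statistic: sum over ordered group pairs i < j of the count of
# (x in group i) < (y in group j), ties counted 1/2.
jt_statistic <- function(values, group_index) {
  k <- max(group_index)
  jt <- 0
  for (i in seq_len(k - 1)) {
    xi <- values[group_index == i]
    for (j in (i + 1):k) {
      xj <- values[group_index == j]
      o <- outer(xi, xj, "<")
      t <- outer(xi, xj, "==")
      jt <- jt + sum(o) + 0.5 * sum(t)
    }
  }
  jt
}

#' Jonckheere-Terpstra test for ordered trend
#'
#' Tests for a monotone trend of a response across ordered groups. The
#' statistic is the sum of pairwise Mann-Whitney "less-than" counts taken
#' in group order; large values indicate an increasing trend. Inference
#' uses the tie-corrected normal approximation, or a Monte-Carlo
#' permutation p-value (fixed internal stream) when any group has fewer
#' than 5 observations or when `permutation = TRUE`.
#'
#' @param values Numeric response.
#' @param groups Ordered group labels (factor with levels in trend order,
#'   or integers).
#' @param alternative `"increasing"`, `"decreasing"` or `"two.sided"`
#'   (default `"two.sided"`).
#' @param permutation Force a permutation p-value.
#' @param n_perm Number of permutations (default 10000).
#' @return An association result (`estimate` = JT statistic) with extras
#'   `z`, `mean`, `var`, `method`.
#' @export
jonckheere_terpstra <- function(values, groups,
                                alternative = c("two.sided", "increasing", "decreasing"),
                                permutation = FALSE, n_perm = 10000L) {
  alternative <- match.arg(alternative)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  gf <- if (is.factor(groups)) droplevels(groups[ok]) else factor(groups[ok])
  gi <- as.integer(gf)
  k <- nlevels(gf)
  if (k < 2) stop("need at least 2 ordered groups")
  nn <- tabulate(gi)
  N <- length(values)
  jt <- jt_statistic(values, gi)
  mu <- (N^2 - sum(nn^2)) / 4
  # tie-corrected null variance (Hollander-Wolfe)
  tj <- table(values)
  A <- N * (N - 1) * (2 * N + 5) - sum(nn * (nn - 1) * (2 * nn + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(nn * (nn - 1) * (nn - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(nn * (nn - 1)) * sum(tj * (tj - 1))
  v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
  z <- if (v > 0) (jt - mu) / sqrt(v) else 0
  use_perm <- permutation || any(nn < 5)
  if (use_perm) {
    # dedicated RNG substream so callers' streams are untouched
    perm_stats <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(20240918L)
      replicate(n_perm, jt_statistic(values, sample(gi)))
    })
    p_inc <- (sum(perm_stats >= jt) + 1) / (n_perm + 1)
    p_dec <- (sum(perm_stats <= jt) + 1) / (n_perm + 1)
    pval <- switch(alternative,
                   increasing = p_inc,
                   decreasing = p_dec,
                   two.sided = min(1, 2 * min(p_inc, p_dec)))
    method <- "permutation"
  } else {
    pval <- switch(alternative,
                   increasing = stats::pnorm(z, lower.tail = FALSE),
                   decreasing = stats::pnorm(z),
                   two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  association_result(
    estimate = jt, p = pval,
    test = paste0("Jonckheere-Terpstra (", method, ")"),
    n = N,
    extra = list(z = z, mean = mu, var = v, method = method, k = k)
  )
}

#' ROC analysis
#'
#' Empirical ROC curve over thresholds at midpoints between unique score
#' values (scores at or above a threshold are called positive), AUC via the
#' Mann-Whitney identity `U / (n1 n0)`, a DeLong placement-based 95% CI,
#' and an operating point chosen by Youden's J or as the lowest threshold
#' achieving a requested sensitivity.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (TRUE/1 = positive class).
#' @param criterion `"youden"` or `"sensitivity"`.
#' @param target_sensitivity Required sensitivity when
#'   `criterion = "sensitivity"` (e.g. 1.0 for a no-false-negative
#'   screening rule).
#' @return A list of class `ldlprs_roc`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci`, `operating_point` (threshold,
#'   sensitivity, specificity, youden).
#' @export
roc_analysis <- function(scores, labels, criterion = c("youden", "sensitivity"),
                         target_sensitivity = 1.0) {
  criterion <- match.arg(criterion)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; pos <- as.logical(labels[ok])
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("ROC undefined: both classes required")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  auc <- auc_mann_whitney(scores, pos)
  # DeLong variance from placement values
  v10 <- vapply(scores[pos], function(s)
    mean((s > scores[!pos]) + 0.5 * (s == scores[!pos])), numeric(1))
  v01 <- vapply(scores[!pos], function(s)
    mean((scores[pos] > s) + 0.5 * (scores[pos] == s)), numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  youden <- sens + spec - 1
  op_idx <- if (criterion == "youden") {
    which.max(youden)
  } else {
    cand <- which(sens >= target_sensitivity - 1e-12)
    cand[which.max(spec[cand])]
  }
  out <- list(thresholds = thr, sensitivity = sens, specificity = spec,
              auc = auc, auc_se = se, auc_ci = ci,
              operating_point = list(threshold = thr[op_idx],
                                     sensitivity = sens[op_idx],
                                     specificity = spec[op_idx],
                                     youden = youden[op_idx]),
              n_positive = n1, n_negative = n0)
  class(out) <- "ldlprs_roc"
  out
}

#' @export
print.ldlprs_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_positive, x$n_negative))
  op <- x$operating_point
  cat(sprintf("Operating point: threshold %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
              op$threshold, 100 * op$sensitivity, 100 * op$specificity))
  invisible(x)
}

#' Compare outcome risk between score-distribution extremes
#'
#' Contrasts outcome prevalence between the top tail (above `top_pct`) and
#' the bottom tail (at or below `bottom_pct`) of a score distribution.
#' Reports the risk ratio with the Katz log-interval and a two-sided
#' Fisher exact p-value.
#'
#' @param scores Numeric scores.
#' @param outcome Binary outcomes.
#' @param top_pct Lower bound (exclusive) percentile of the top tail
#'   (default 90).
#' @param bottom_pct Upper bound (inclusive) percentile of the bottom tail
#'   (default 10).
#' @return An association result (`estimate` = risk ratio) with extras
#'   `prevalence_top`, `prevalence_bottom`, `n_top`, `n_bottom`.
#' @export
extreme_percentile_comparison <- function(scores, outcome,
                                          top_pct = 90, bottom_pct = 10) {
  ok <- !is.na(scores) & !is.na(outcome)
  scores <- scores[ok]; y <- as.logical(outcome[ok])
  pr <- percentile_rank(scores)
  top <- pr > top_pct
  bottom <- pr <= bottom_pct
  if (!any(top) || !any(bottom)) stop("empty tail: adjust percentile cuts")
  a <- sum(y[top]); n1 <- sum(top)
  c_ <- sum(y[bottom]); n0 <- sum(bottom)
  p1 <- a / n1; p0 <- c_ / n0
  rr <- if (p0 > 0) p1 / p0 else Inf
  # Katz log CI (0.5 correction when a zero cell would break the SE)
  aa <- a; cc <- c_
  if (a == 0 || c_ == 0) { aa <- a + 0.5; cc <- c_ + 0.5 }
  se <- sqrt(1 / aa - 1 / n1 + 1 / cc - 1 / n0)
  lrr <- log((aa / n1) / (cc / n0))
  fp <- stats::fisher.test(matrix(c(a, n1 - a, c_, n0 - c_), 2))$p.value
  association_result(
    estimate = rr,
    ci_low = exp(lrr - 1.96 * se), ci_high = exp(lrr + 1.96 * se),
    p = fp,
    test = "risk ratio, extreme percentiles (Katz CI, Fisher p)",
    n = n1 + n0,
    extra = list(prevalence_top = p1, prevalence_bottom = p0,
                 n_top = n1, n_bottom = n0)
  )
}
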