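test_that("2x2 odds ratios handle null association, zero cells and degeneracy", {
  r <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(r$estimate, 1)
  expect_gt(r$p, 0.99)
  rz <- odds_ratio_2x2(5, 0, 3, 7)
  expect_true(rz$corrected)
  expect_equal(rz$estimate, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "degenerate")
})

test_that("logistic MLE on a 2x2 equals the cross-product odds ratio", {
  set.seed(71)
  for (k in 1:15) {
    tab <- matrix(sample(3:60, 4), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    y <- rep(c(1, 1, 0, 0), c(a, b, c_, d))
    x <- rep(c(1, 0, 1, 0), c(a, b, c_, d))
    fit <- logistic_fit(y, data.frame(x = x))
    or_glm <- fit$coefficients$or[fit$coefficients$term == "x"]
    expect_equal(or_glm, odds_ratio_2x2(a, b, c_, d)$estimate, tolerance = 1e-6)
  }
})

test_that("intercept-only logistic fit returns the log-odds of the case fraction", {
  y <- rep(c(1, 0), c(125, 97))
  fit <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
  expect_equal(unname(coef(fit)), log(125 / 97), tolerance = 1e-6)
  # and the package fit agrees through a constant-free single covariate
  f2 <- suppressWarnings(logistic_fit(y, data.frame(x = rep(0, 222))))  # constant covariate: rank warning expected
  expect_equal(f2$coefficients$beta[1], log(125 / 97), tolerance = 1e-6)
})

test_that("logistic fit reports separation on perfectly separable data", {
  y <- rep(c(0, 1), each = 20)
  x <- c(rnorm(20, -5), rnorm(20, 5))
  expect_warning(fit <- logistic_fit(y, data.frame(x = x)), "separation")
  expect_true(fit$separation)
})

test_that("Hosmer-Lemeshow has g - 2 df and collapses under constant risk", {
  set.seed(81)
  p <- runif(500, 0.05, 0.95)
  y <- rbinom(500, 1, p)
  hl <- hosmer_lemeshow(p, y, g = 10)
  expect_equal(hl$df, 8)
  # constant fitted probability equal to the outcome rate: no signal
  suppressMessages(hl0 <- hosmer_lemeshow(rep(0.3, 100), rbinom(100, 1, 0.3)))
  expect_lt(hl0$estimate, 1e-6)
})

test_that("Hosmer-Lemeshow statistic is near its df under correct calibration", {
  set.seed(82)
  stats_ <- replicate(120, {
    x <- rnorm(400)
    p <- plogis(-0.3 + 0.8 * x)
    y <- rbinom(400, 1, p)
    fit <- glm(y ~ x, family = binomial())
    hosmer_lemeshow(fitted(fit), y)$estimate
  })
  expect_equal(mean(stats_), 8, tolerance = 1.6)
})

test_that("nested model comparison is zero for identical models and detects real signal", {
  set.seed(91)
  x1 <- rnorm(400); x2 <- rnorm(400)
  y <- rbinom(400, 1, plogis(0.5 * x1 + 0.9 * x2))
  m1 <- logistic_fit(y, data.frame(x1 = x1))
  m12 <- logistic_fit(y, data.frame(x1 = x1, x2 = x2))
  same <- nested_model_compare(m1, m1)
  expect_equal(same$estimate, 0)
  expect_equal(same$p, 1)
  cmp <- nested_model_compare(m1, m12)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$auc_large, cmp$auc_small)
  expect_error(nested_model_compare(m12, m1), "not nested")
})

test_that("adding a pure-noise covariate rejects at about the nominal rate", {
  set.seed(92)
  rej <- replicate(200, {
    x <- rnorm(250)
    y <- rbinom(250, 1, plogis(0.6 * x))
    noise <- rnorm(250)
    cmp <- nested_model_compare(
      logistic_fit(y, data.frame(x = x)),
      logistic_fit(y, data.frame(x = x, noise = noise)))
    cmp$p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("standardized simple-regression slope equals the Pearson correlation", {
  set.seed(101)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  r <- linear_fit_standardized(y, x)
  expect_equal(r$estimate, cor(x, y), tolerance = 1e-12)
  ident <- suppressWarnings(linear_fit_standardized(1:10, 1:10))  # perfect fit
  expect_equal(ident$estimate, 1, tolerance = 1e-12)
  expect_error(linear_fit_standardized(rnorm(10), rep(1, 10)), "degenerate")
})

test_that("Spearman correlation matches hand rank arithmetic", {
  # d^2 = (1,1,1,1,0): rho = 1 - 6*4/(5*24) = 0.8
  r <- spearman_corr(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$estimate, 0.8, tolerance = 1e-12)
  x <- rexp(30)
  expect_equal(spearman_corr(x, log(x) + 5)$estimate, 1)
  expect_equal(spearman_corr(1:10, 10:1)$estimate, -1)
  expect_error(spearman_corr(1:5, rep(1, 5)), "constant")
})

test_that("Mann-Whitney U and exact p match enumeration on small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$estimate, 0)
  expect_equal(r$p, 1 / 20)  # 1 of C(6,3) arrangements is as extreme
  expect_equal(mann_whitney(1, 2)$estimate, 0)
  big <- mann_whitney(rnorm(30), rnorm(30))
  expect_match(big$test, "normal")
})

test_that("Jonckheere-Terpstra reduces to the two-group Mann-Whitney count", {
  set.seed(111)
  for (k in 1:10) {
    a <- rnorm(9); b <- rnorm(12)
    jt <- jonckheere_terpstra(c(a, b), rep(1:2, c(9, 12)))
    u_ab <- mann_whitney(a, b)$estimate  # count of a > b pairs
    expect_equal(jt$estimate, 9 * 12 - u_ab)
  }
})

test_that("Jonckheere-Terpstra attains its maximum on perfectly ordered groups", {
  jt <- jonckheere_terpstra(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2),
                            alternative = "increasing")
  expect_equal(jt$estimate, 12)  # all 3 * 4 cross-group pairs concordant
  # only 1 of the 90 distinct assignments reaches JT = 12
  expect_lt(jt$p, 0.03)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration on tiny instances", {
  set.seed(121)
  v <- c(0.3, 1.9, 0.8, 2.5, 1.1, 3.0)
  exact <- jt_exact_p(v, c(2, 2, 2))
  jt <- jonckheere_terpstra(v, rep(1:3, each = 2), alternative = "increasing",
                            permutation = TRUE, n_perm = 20000)
  expect_lt(abs(jt$p - exact), 0.015)
})

test_that("ROC AUC equals the rank-sum identity and survives monotone transforms", {
  perfect <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  set.seed(131)
  for (k in 1:50) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    s <- c(rnorm(n0), rnorm(n1, 0.6))
    lab <- rep(c(0, 1), c(n0, n1))
    roc <- roc_analysis(s, lab)
    w <- wilcox.test(s[lab == 1], s[lab == 0], exact = FALSE)$statistic
    expect_equal(roc$auc, unname(w) / (n1 * n0), tolerance = 1e-12)
    roc2 <- roc_analysis(exp(s), lab)
    expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
  }
})

test_that("AUC and DeLong interval agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(141)
  s <- c(rnorm(60), rnorm(80, 0.8))
  lab <- rep(c(0, 1), c(60, 80))
  ours <- roc_analysis(s, lab)
  ref <- pROC::roc(lab, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$auc_ci[1], ci[1], tolerance = 0.002)
  expect_equal(ours$auc_ci[2], ci[3], tolerance = 0.002)
})

test_that("the fixed-sensitivity operating point never misses positives", {
  set.seed(151)
  s <- c(rnorm(100), rnorm(20, 1))
  lab <- rep(c(0, 1), c(100, 20))
  roc <- roc_analysis(s, lab, criterion = "sensitivity", target_sensitivity = 1)
  expect_equal(roc$operating_point$sensitivity, 1)
  expect_true(all(s[lab == 1] >= roc$operating_point$threshold))
})

test_that("extreme-percentile risk ratios match direct prevalence arithmetic", {
  scores <- 1:100
  outcome <- c(rep(FALSE, 90), rep(TRUE, 10))  # all events in the top decile
  outcome[1:5] <- TRUE                          # plus half the bottom decile
  r <- extreme_percentile_comparison(scores, outcome)
  expect_equal(r$prevalence_top, 1.0)
  expect_equal(r$prevalence_bottom, 0.5)
  expect_equal(r$estimate, 2.0)
  same <- extreme_percentile_comparison(scores, rep(c(TRUE, FALSE), 50))
  expect_equal(same$estimate, 1.0)
  expect_equal(same$p, 1)
})

test_that("marginal significance band covers p in (0.05, 0.15]", {
  expect_true(association_result(1, p = 0.10)$marginal)
  expect_false(association_result(1, p = 0.04)$marginal)
  expect_false(association_result(1, p = 0.2)$marginal)
})
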