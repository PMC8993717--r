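make_two_group <- function(n1 = 30, n2 = 12, shift = 0, skew = FALSE,
                           seed = 1) {
  withr::with_seed(seed, {
    x1 <- if (skew) rexp(n1) else rnorm(n1)
    x2 <- (if (skew) rexp(n2) else rnorm(n2)) + shift
    data.frame(value = c(x1, x2),
               label = factor(rep(c("stable", "ctrcd"), c(n1, n2)),
                              levels = c("stable", "ctrcd")))
  })
}

test_that("normality gate selects t for normal and rank for skewed data", {
  co <- make_two_group(seed = 2)
  out <- compare_feature(co, "value")
  expect_equal(out$test, "t")
  expect_true(out$p >= 0 && out$p <= 1)

  co2 <- make_two_group(n1 = 80, n2 = 40, skew = TRUE, seed = 4)
  out2 <- compare_feature(co2, "value")
  expect_equal(out2$test, "rank")
})

test_that("compare_feature detects a real separation and rejects degenerates", {
  co <- make_two_group(n1 = 60, n2 = 20, shift = 3, seed = 5)
  expect_lt(compare_feature(co, "value")$p, 1e-6)

  co$value[co$label == "ctrcd"] <- 1
  expect_error(compare_feature(co, "value"), "degenerate")
  expect_error(compare_feature(co[c(1, 2, 31, 32), ], "value"), "at least 3")
})

test_that("Hotelling T2: null, algebraic identity with t, and errors", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  same <- hotelling_t2(X, X)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p.value, 1)

  # p = 1 reduces to the squared equal-variance two-sample t statistic
  x1 <- rnorm(25, 0); x2 <- rnorm(15, 0.8)
  ht <- hotelling_t2(matrix(x1), matrix(x2))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(ht$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht$p.value, tt$p.value, tolerance = 1e-10)

  # affine invariance
  Y1 <- matrix(rnorm(80), 40, 2); Y2 <- matrix(rnorm(44, 0.5), 22, 2)
  A <- matrix(c(2, 1, 0.5, 3), 2, 2); b <- c(10, -4)
  h1 <- hotelling_t2(Y1, Y2)
  h2 <- hotelling_t2(sweep(Y1 %*% A, 2, b, "+"), sweep(Y2 %*% A, 2, b, "+"))
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-8)

  expect_error(hotelling_t2(Y1[1:2, ], Y2[1:2, ]), "sample size")
  Z <- cbind(Y1[, 1], Y1[, 1])  # collinear -> singular pooled covariance
  expect_error(hotelling_t2(Z, Z + 1), "singular")
})

test_that("Henze-Zirkler accepts normal and rejects heavy-skew samples", {
  set.seed(7)
  X <- matrix(rnorm(400), 200, 2)
  hzn <- henze_zirkler(X)
  expect_gt(hzn$p.value, 0.01)
  Xs <- matrix(rexp(400), 200, 2)
  expect_lt(henze_zirkler(Xs)$p.value, 0.001)
  expect_error(henze_zirkler(matrix(rnorm(4), 2, 2)), "observations")
})

test_that("logistic models fit, test, and refuse unusable outcomes", {
  co <- make_cohort(cohort_spec(n_stable = 300, n_ctrcd = 60, rho = -0.3,
                                seed = 9))
  for (mm in c("full", "reduced")) {
    fit <- fit_logistic(co, mm)
    expect_s3_class(fit, "logistic_result")
    expect_true(fit$auc >= 0 && fit$auc <= 1)
    expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
    expect_true(fit$model_p < 0.05)  # groups differ in ApEn and LVEF
  }
  expect_equal(nrow(fit_logistic(co, "reduced")$coefficients), 4)
  expect_equal(nrow(fit_logistic(co, "full")$coefficients), 7)

  co1 <- co[co$label == "stable", ]
  expect_error(fit_logistic(co1, "reduced"), "classes")

  # perfectly separated outcome must error, not return huge estimates
  sep <- co
  sep$apen <- ifelse(sep$label == "ctrcd", 2, 0.1)
  expect_error(fit_logistic(sep, "reduced"), "separation|stable")
})

test_that("AUC follows the Mann-Whitney definition", {
  expect_equal(auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # pos {3, 2}, neg {1, 2}: (1 + 1 + 1 + 0.5)/4
  expect_equal(auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "classes")
  # invariance under strictly increasing transforms
  set.seed(10)
  s <- runif(40); l <- runif(40) < 0.4
  expect_equal(auc(s, l), auc(exp(5 * s), l))
  expect_equal(auc(s, l), auc(rank(s), l))
})

test_that("baseline exclusion filters and accounts by category", {
  co <- data.frame(id = 1:5, lvef_baseline = c(60, 54, 70, 58, 62))
  out <- exclude_baseline(co)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "exclusion_report")[["lvef"]], 1)

  out2 <- exclude_baseline(data.frame(lvef_baseline = c(60, 70)))
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "exclusion_report")[["lvef"]], 0)

  co3 <- data.frame(lvef_baseline = c(60, 54, 70), gating = c(TRUE, FALSE, FALSE))
  out3 <- exclude_baseline(co3, quality_flags = "gating")
  expect_equal(nrow(out3), 1)
  expect_equal(attr(out3, "exclusion_report")[["gating"]], 1)
})

test_that("cross-validated classifiers are stratified, seeded, and sane", {
  co <- make_cohort(cohort_spec(n_stable = 80, n_ctrcd = 20, seed = 11))
  cv1 <- cv_classifiers(co, folds = 5, repeats = 2, seed = 1, ntree = 40)
  cv2 <- cv_classifiers(co, folds = 5, repeats = 2, seed = 1, ntree = 40)
  expect_identical(cv1$rf$aucs, cv2$rf$aucs)
  expect_identical(cv1$nb$aucs, cv2$nb$aucs)
  expect_equal(cv1$rf$n_valid + cv1$rf$n_skipped, 10)
  # groups differ in ApEn/LVEF: classifiers must beat chance clearly
  expect_gt(cv1$rf$mean_auc, 0.6)
  expect_gt(cv1$nb$mean_auc, 0.6)

  # strongly separated groups are nearly perfectly ranked
  sep <- co
  sep$apen <- ifelse(sep$label == "ctrcd", rnorm(20, 5, 0.2),
                     rnorm(80, 0, 0.2))
  cvs <- cv_classifiers(sep, folds = 5, repeats = 1, seed = 2, ntree = 40)
  expect_gt(cvs$rf$mean_auc, 0.95)
  expect_gt(cvs$nb$mean_auc, 0.95)
})

test_that("classifier internals rank an obvious signal correctly", {
  withr::with_seed(13, {
    X <- cbind(a = c(rnorm(40, 0), rnorm(40, 3)), b = rnorm(80))
    y <- rep(c(FALSE, TRUE), each = 40)
    rf <- rnvgphase:::rf_fit(X, y, ntree = 50)
    expect_gt(auc(rnvgphase:::rf_predict(rf, X), y), 0.95)
    nb <- rnvgphase:::nb_fit(X, y)
    expect_gt(auc(rnvgphase:::nb_predict(nb, X), y), 0.95)
    # single-row prediction works
    expect_length(rnvgphase:::rf_predict(rf, X[1, , drop = FALSE]), 1)
    expect_length(rnvgphase:::nb_predict(nb, X[1, , drop = FALSE]), 1)
  })
})
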