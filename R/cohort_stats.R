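#' Normality-gated two-group comparison of one feature
#'
#' Shapiro-Wilk normality is checked in each group; when both groups are
#' compatible with normality (p >= alpha) the groups are compared with
#' Welch's unequal-variance t test, otherwise with the two-sided
#' Mann-Whitney rank-sum test.
#'
#' @param cohort a `cohort_table` with a `label` column (stable/ctrcd).
#' @param feature column name to compare.
#' @param alpha significance level for the normality gate.
#' @return one-row `data.frame`: feature, test used, statistic, p-value,
#'   per-group mean and SD, per-group Shapiro p.
#' @export
compare_feature <- function(cohort, feature, alpha = 0.05) {
  x <- split(cohort[[feature]], cohort$label)
  x1 <- x$stable; x2 <- x$ctrcd
  if (length(x1) < 3 || length(x2) < 3) {
    stop_rnvg("both groups need at least 3 members",
              class = "rnvg_validation_error")
  }
  if (sd(x1) == 0 || sd(x2) == 0) {
    stop_rnvg("feature '", feature, "' is degenerate (zero variance) in a group",
              class = "rnvg_validation_error")
  }
  sw1 <- shapiro.test(x1)$p.value
  sw2 <- shapiro.test(x2)$p.value
  if (sw1 >= alpha && sw2 >= alpha) {
    tt <- t.test(x1, x2)       # Welch
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- wilcox.test(x1, x2, exact = FALSE)
    test <- "rank"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  data.frame(feature = feature, test = test, statistic = statistic,
             p = p, mean_stable = mean(x1), sd_stable = sd(x1),
             mean_ctrcd = mean(x2), sd_ctrcd = sd(x2),
             shapiro_stable = sw1, shapiro_ctrcd = sw2,
             row.names = NULL)
}

#' Two-sample Hotelling T-squared test
#'
#' Multivariate generalization of the two-sample t test:
#' \deqn{T^2 = \frac{n_1 n_2}{n_1 + n_2}
#'   (\bar x_1 - \bar x_2)^\top S_{pooled}^{-1} (\bar x_1 - \bar x_2)}
#' converted to an F statistic with (p, n1 + n2 - p - 1) degrees of
#' freedom.
#'
#' @param X1,X2 per-group numeric matrices (rows = subjects, columns =
#'   features).
#' @return list with `statistic` (T^2), `F`, `df` (c(p, n1+n2-p-1)),
#'   `p.value`.
#' @export
hotelling_t2 <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  p <- ncol(X1)
  stopifnot(ncol(X2) == p)
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (n1 + n2 <= p + 2) {
    stop_rnvg("combined sample size must exceed the feature count + 2",
              class = "rnvg_validation_error")
  }
  d <- colMeans(X1) - colMeans(X2)
  Sp <- ((n1 - 1) * cov(X1) + (n2 - 1) * cov(X2)) / (n1 + n2 - 2)
  Si <- tryCatch(solve(Sp), error = function(e) {
    stop_rnvg("pooled covariance is singular; reduce or decorrelate the ",
              "feature set", class = "rnvg_validation_error")
  })
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Si %*% d)
  Fstat <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2
  df <- c(p, n1 + n2 - p - 1)
  list(statistic = T2, F = Fstat, df = df,
       p.value = pf(Fstat, df[1], df[2], lower.tail = FALSE))
}

#' Henze-Zirkler test of multivariate normality
#'
#' Smooth test based on the weighted L2 distance between the empirical
#' characteristic function of the standardized sample and that of the
#' multivariate normal; the p-value uses the standard lognormal
#' approximation to the null distribution of the statistic.
#'
#' @param X numeric matrix, rows = observations.
#' @return list with `statistic` (HZ), `p.value`.
#' @export
henze_zirkler <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_rnvg("need more observations than dimensions",
                        class = "rnvg_validation_error")
  S <- cov(X) * (n - 1) / n
  Si <- tryCatch(solve(S), error = function(e) {
    stop_rnvg("sample covariance is singular", class = "rnvg_validation_error")
  })
  Xc <- sweep(X, 2, colMeans(X))
  # pairwise and to-mean squared Mahalanobis distances
  G <- Xc %*% Si %*% t(Xc)
  Di <- diag(G)
  Dij <- outer(Di, Di, "+") - 2 * G
  b <- ((2 * p + 1) * n / 4)^(1 / (p + 4)) / sqrt(2)
  HZ <- n * (mean(exp(-b^2 / 2 * Dij)) -
               2 * (1 + b^2)^(-p / 2) * mean(exp(-b^2 / (2 * (1 + b^2)) * Di)) +
               (1 + 2 * b^2)^(-p / 2))
  # lognormal approximation to the null
  a <- 1 + 2 * b^2
  wb <- (1 + b^2) * (1 + 3 * b^2)
  mu <- 1 - a^(-p / 2) * (1 + p * b^2 / a + p * (p + 2) * b^4 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b^2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b^4 / a^2 + 3 * p * (p + 2) * b^8 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b^4 / (2 * wb) +
                         p * (p + 2) * b^8 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
  psi <- sqrt(log((si2 + mu^2) / mu^2))
  list(statistic = HZ,
       p.value = plnorm(HZ, meanlog = pmu, sdlog = psi, lower.tail = FALSE))
}

#' Logistic regression models for cardiotoxicity risk
#'
#' Fits the two risk models by maximum likelihood: the full model uses
#' every phase parameter plus the ApEn-by-baseline-LVEF interaction; the
#' reduced model keeps only ApEn, baseline LVEF and their interaction.
#' Complete separation or non-convergence — a real hazard with few
#' events — raises an error rather than returning unstable estimates.
#'
#' @param cohort a `cohort_table` with `label` and feature columns.
#' @param model `"full"` or `"reduced"`.
#' @return list of class `logistic_result`: `coefficients` (data.frame
#'   with estimate, se, Wald z and p per predictor), `model_chisq`,
#'   `model_df`, `model_p` (likelihood-ratio test against the null
#'   model), `auc` (in-sample), and the `glm` `fit`.
#' @export
fit_logistic <- function(cohort, model = c("full", "reduced")) {
  model <- match.arg(model)
  if (length(unique(cohort$label)) < 2) {
    stop_rnvg("both outcome classes must be present",
              class = "rnvg_validation_error")
  }
  cohort$y <- as.integer(cohort$label == "ctrcd")
  form <- switch(model,
    full = y ~ apen * lvef_baseline + synchrony + entropy + phase_sd,
    reduced = y ~ apen * lvef_baseline
  )
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = cohort, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || sep) {
    stop_rnvg("logistic model did not yield stable estimates (",
              if (sep) "complete or quasi-complete separation" else "non-convergence",
              "); with very few events consider the reduced model or penalization",
              class = "rnvg_model_error")
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(predictor = rownames(sm), estimate = sm[, 1],
                      se = sm[, 2], z = sm[, 3], p = sm[, 4],
                      row.names = NULL)
  chisq <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  structure(list(
    model = model, coefficients = coefs,
    model_chisq = chisq, model_df = df,
    model_p = pchisq(chisq, df, lower.tail = FALSE),
    auc = auc(fitted(fit), cohort$y == 1),
    fit = fit
  ), class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("logistic model '%s': LR chi-sq %.2f (df %d, p %.3g), in-sample AUC %.3f\n",
              x$model, x$model_chisq, x$model_df, x$model_p, x$auc))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counted one half.
#' Invariant under any strictly increasing transform of the scores.
#'
#' @param scores numeric risk scores.
#' @param labels logical (or coercible) vector, `TRUE` = positive.
#' @return value in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_rnvg("both classes must be present", class = "rnvg_validation_error")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exclude records below the baseline-quality bar
#'
#' Removes records whose baseline LVEF is under `lvef_floor` or that
#' carry a quality flag (e.g. ECG-gating problems, non-diagnostic
#' scans), and accounts for each exclusion category.
#'
#' @param cohort data.frame with `lvef_baseline`; optional logical
#'   columns named in `quality_flags`.
#' @param lvef_floor baseline LVEF floor in percent (default 55).
#' @param quality_flags names of logical columns; a `TRUE` excludes.
#' @return filtered cohort with attribute `exclusion_report`: named
#'   counts per category plus `remaining`.
#' @export
exclude_baseline <- function(cohort, lvef_floor = 55,
                             quality_flags = character(0)) {
  drop_low <- cohort$lvef_baseline < lvef_floor
  report <- c(lvef = sum(drop_low))
  drop_any <- drop_low
  for (fl in quality_flags) {
    hit <- isTRUE_vec(cohort[[fl]]) & !drop_any
    report[fl] <- sum(hit)
    drop_any <- drop_any | isTRUE_vec(cohort[[fl]])
  }
  out <- cohort[!drop_any, , drop = FALSE]
  report <- c(report, remaining = nrow(out))
  attr(out, "exclusion_report") <- report
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Repeated stratified cross-validated classifiers
#'
#' Fits a random forest and a Gaussian naive Bayes classifier to the
#' phase-parameter feature set under repeated stratified k-fold
#' cross-validation, reporting the AUC of each held-out resample. Folds
#' are stratified by outcome — with ~11 events in ~177 patients,
#' unstratified folds would frequently contain no event at all. Any
#' resample whose held-out fold still ends up single-class is skipped
#' with a warning count.
#'
#' @param cohort a `cohort_table`.
#' @param features predictor columns.
#' @param folds,repeats cross-validation geometry (default 10 x 3).
#' @param seed integer seed controlling fold assignment and forest
#'   bootstraps; identical seeds give identical resamples and AUCs.
#' @param methods subset of `c("rf", "nb")`.
#' @param ntree trees per forest.
#' @return named list of `cv_result` objects: `aucs` (per valid
#'   resample), `mean_auc`, `n_valid`, `n_skipped`.
#' @export
cv_classifiers <- function(cohort,
                           features = c("apen", "synchrony", "entropy",
                                        "phase_sd", "lvef_baseline"),
                           folds = 10, repeats = 3, seed = NULL,
                           methods = c("rf", "nb"), ntree = 100) {
  methods <- match.arg(methods, several.ok = TRUE)
  X <- as.matrix(cohort[features])
  y <- cohort$label == "ctrcd"
  if (sum(y) == 0 || sum(!y) == 0) {
    stop_rnvg("both classes must be present", class = "rnvg_validation_error")
  }
  with_seed_if(seed, {
    assignments <- lapply(seq_len(repeats), function(rep)
      stratified_folds(y, folds))
    out <- list()
    for (mth in methods) {
      aucs <- numeric(0); skipped <- 0
      for (rep in seq_len(repeats)) {
        fold_id <- assignments[[rep]]
        for (f in seq_len(folds)) {
          test <- fold_id == f
          if (length(unique(y[test])) < 2 || length(unique(y[!test])) < 2) {
            skipped <- skipped + 1
            warning("skipping a single-class resample", call. = FALSE)
            next
          }
          scores <- if (mth == "rf") {
            fit <- rf_fit(X[!test, , drop = FALSE], y[!test], ntree = ntree)
            rf_predict(fit, X[test, , drop = FALSE])
          } else {
            fit <- nb_fit(X[!test, , drop = FALSE], y[!test])
            nb_predict(fit, X[test, , drop = FALSE])
          }
          aucs <- c(aucs, auc(scores, y[test]))
        }
      }
      out[[mth]] <- structure(
        list(method = mth, aucs = aucs, mean_auc = mean(aucs),
             n_valid = length(aucs), n_skipped = skipped),
        class = "cv_result")
    }
    out
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: mean AUC %.3f over %d resamples (%d skipped)\n",
              x$method, x$mean_auc, x$n_valid, x$n_skipped))
  invisible(x)
}

# internal: per-class cyclic fold assignment after a shuffle
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}
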