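test_that("elliptical ROI matches an enumeration oracle and its symmetries", {
  roi <- make_lv_roi(c(64, 64), c(32, 32), c(10, 14))
  # independent pixel enumeration
  n <- 0L
  for (r in 1:64) for (c in 1:64) {
    if (((r - 32) / 10)^2 + ((c - 32) / 14)^2 <= 1) n <- n + 1L
  }
  expect_equal(sum(roi), n)
  expect_gt(sum(roi), 400)
  expect_lt(sum(roi), 480)
  # mirror symmetry about both axes through the center
  expect_identical(roi[32 - (0:9), ], roi[32 + (0:9), ])
  expect_identical(roi[, 32 - (0:13)], roi[, 32 + (0:13)])
})

test_that("degenerate ellipses error", {
  # off-lattice center: no pixel within 0.4 of it
  expect_error(make_lv_roi(c(64, 64), c(32.5, 32.5), c(0.4, 0.4)), "empty")
  expect_error(make_lv_roi(c(20, 20), c(10, 10), c(15, 3)), "fit")
})

test_that("phase image generator honors segment means and SDs", {
  roi <- make_lv_roi()
  pm0 <- make_phase_image(roi, means = 140, sds = 0)
  expect_true(all(pm0$phase[roi] == 140))
  expect_equal(approximate_entropy(serpentine_series(pm0, roi)), 0)

  # 8 equal means, sd 5: pooled SD tracks the generator parameter
  sds <- vapply(1:20, function(s) {
    phase_sd(make_phase_image(roi, means = rep(140, 8), sds = 5, seed = s),
             roi)
  }, numeric(1))
  se <- 5 / sqrt(2 * (sum(roi) - 1))
  expect_lt(abs(mean(sds) - 5), 3 * se / sqrt(20) + 0.05)

  expect_error(make_phase_image(roi, means = c(NA, 100)), "finite")
})

test_that("generators are pure functions of their seed", {
  roi <- tiny_roi()
  a <- make_phase_image(roi, means = rep(140, 8), sds = 5, seed = 7)
  b <- make_phase_image(roi, means = rep(140, 8), sds = 5, seed = 7)
  expect_identical(a, b)
  s1 <- make_gated_study(a, roi, seed = 3)
  s2 <- make_gated_study(a, roi, seed = 3)
  expect_identical(s1$frames, s2$frames)
  expect_false(identical(
    s1$frames, make_gated_study(a, roi, seed = 4)$frames))
})

test_that("seeded generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_phase_image(tiny_roi(), means = 140, sds = 5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("presets exist, differ as intended, and reject unknown names", {
  roi <- make_lv_roi()
  for (nm in c("normal", "mi", "lbbb", "aneurysm")) {
    pm <- preset_phase_image(nm, roi, seed = 1)
    expect_s3_class(pm, "phase_map")
    expect_true(all(pm$phase[roi] >= 0 & pm$phase[roi] < 360))
  }
  expect_error(preset_phase_image("ischemia", roi), "arg")
  # normal contraction is tightly synchronous (20-seed slice of the
  # 100-seed acceptance check)
  syn <- vapply(1:20, function(s) {
    synchrony(preset_phase_image("normal", roi, seed = s), roi = roi)
  }, numeric(1))
  expect_true(all(syn > 0.95))
  # the aneurysm's two blocks put mass far apart: SD well above normal
  expect_gt(phase_sd(preset_phase_image("aneurysm", roi, seed = 2), roi),
            phase_sd(preset_phase_image("normal", roi, seed = 2), roi))
})

test_that("gated-study simulation respects its feasibility contract", {
  roi <- tiny_roi()
  pm <- preset_phase_image("normal", roi, seed = 1)
  expect_error(make_gated_study(pm, roi, modulation = 1.4), "modulation")
  expect_error(make_gated_study(pm, roi, total_counts = 0), "positive")
  expect_error(make_gated_study(pm, roi, F = 3), ">= 4")
  st <- make_gated_study(pm, roi, total_counts = 2e5, seed = 5)
  expect_true(all(st$frames >= 0))
  expect_equal(sum(st$frames) / 2e5, 1, tolerance = 0.02)
  # expectation mode totals are exact up to the stated approximation
  st0 <- make_gated_study(pm, roi, total_counts = 2e5, noise = "none")
  expect_equal(sum(st0$frames), 2e5, tolerance = 1e-6)
})

test_that("cohort moments recover the generator parameters", {
  spec <- cohort_spec(seed = 20260912)
  cohort <- make_cohort(spec)
  expect_equal(nrow(cohort), 177)
  expect_equal(as.integer(table(cohort$label)[c("stable", "ctrcd")]),
               c(166, 11))
  for (f in c("apen", "synchrony", "entropy", "phase_sd")) {
    xs <- cohort[[f]][cohort$label == "stable"]
    se <- spec$stable_sd[f] / sqrt(166)
    expect_lt(abs(mean(xs) - spec$stable_mean[f]), 3 * se + 1e-12)
  }
  # baseline LVEF is floor-truncated, so only a one-sided sanity bound
  expect_true(all(cohort$lvef_baseline >= 55))
  expect_lt(abs(mean(cohort$lvef_baseline[cohort$label == "stable"]) - 73.5),
            3 * 6.1 / sqrt(166) + 0.5)
})

test_that("tiny cohorts and feature correlations work", {
  c2 <- make_cohort(cohort_spec(n_stable = 1, n_ctrcd = 1, seed = 4))
  expect_equal(nrow(c2), 2)
  expect_equal(as.character(sort(unique(c2$label))), c("stable", "ctrcd"))
  expect_equal(as.character(c2$label), as.character(c2$group))

  # apen-lvef correlation tracks rho within 3 SE (stable group, n=600)
  for (rho in c(0, -0.5)) {
    co <- make_cohort(cohort_spec(n_stable = 600, n_ctrcd = 1, rho = rho,
                                  seed = 31 + round(10 * abs(rho))))
    r_hat <- cor(co$apen[co$label == "stable"],
                 co$lvef_baseline[co$label == "stable"])
    expect_lt(abs(r_hat - rho), 3 / sqrt(600) + 0.05)
  }
})

test_that("labeling applies the guideline rule with flagged edge cases", {
  rec <- data.frame(
    id = c("a", "b", "c", "d"),
    lvef_baseline = c(65, 75, 58, 70),
    fu_1 = c(48, 62, 49, 69),
    fu_2 = c(60, NA, 57, NA)
  )
  out <- label_groups(rec)
  expect_equal(as.character(out$label), c("ctrcd", "stable", "stable", "stable"))
  # b: drop 13 but nadir >= 50 -> flagged; c: nadir 49 but drop 9 -> flagged
  expect_equal(out$flag, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$max_lvef_drop, c(17, 13, 9, 1))
  expect_error(label_groups(data.frame(lvef_baseline = 60, fu_1 = NA_real_)),
               "follow-up")
  expect_error(label_groups(data.frame(lvef_baseline = 60)), "fu_")
})

test_that("generated cohorts survive their own labeling rule exactly", {
  for (s in c(2, 17, 123)) {
    co <- make_cohort(cohort_spec(n_stable = 40, n_ctrcd = 5, seed = s))
    relabeled <- label_groups(co[setdiff(names(co),
                                         c("label", "max_lvef_drop", "flag"))])
    expect_equal(as.character(relabeled$label), as.character(co$group))
  }
})
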