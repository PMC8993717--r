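#' Elliptical left-ventricle ROI mask
#'
#' Stand-in for a manually drawn LV region: pixels whose normalized
#' elliptic distance from `center` is at most 1 are inside.
#'
#' @param grid_shape c(rows, cols), default 64 x 64.
#' @param center c(row, col) of the ellipse center.
#' @param semi_axes c(row semi-axis, col semi-axis) in pixels.
#' @return logical matrix.
#' @export
make_lv_roi <- function(grid_shape = c(64, 64), center = c(32, 32),
                        semi_axes = c(10, 14)) {
  stopifnot(length(grid_shape) == 2, length(center) == 2, length(semi_axes) == 2)
  if (center[1] - semi_axes[1] < 1 || center[1] + semi_axes[1] > grid_shape[1] ||
      center[2] - semi_axes[2] < 1 || center[2] + semi_axes[2] > grid_shape[2]) {
    stop_rnvg("ellipse does not fit inside the grid", class = "rnvg_validation_error")
  }
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  d <- ((rows - center[1]) / semi_axes[1])^2 + ((cols - center[2]) / semi_axes[2])^2
  roi <- d <= 1
  if (!any(roi)) {
    stop_rnvg("ROI is empty: semi-axes too small", class = "rnvg_validation_error")
  }
  roi
}

# internal: 1-based radial sector index for each ROI pixel; sector 1
# starts at 12 o'clock and sectors advance clockwise (toward 3 o'clock)
roi_sectors <- function(roi, n_segments) {
  idx <- which(roi, arr.ind = TRUE)
  cen <- colMeans(idx)
  dy <- idx[, 1] - cen[1]   # down is +row
  dx <- idx[, 2] - cen[2]
  ang <- (atan2(dx, -dy) * 180 / pi) %% 360
  sec <- pmin(floor(ang / (360 / n_segments)) + 1L, n_segments)
  list(idx = idx, sector = sec)
}

#' Simulated phase image with per-segment mean and SD
#'
#' Divides the ROI into `length(means)` equal angular sectors about its
#' centroid (sector 1 at 12 o'clock, clockwise) and draws each pixel's
#' phase from a normal distribution with that sector's mean and SD,
#' clamped to \[0, 360) — clamping rather than wrapping, since a wrapped
#' value would alias late contraction as early. Amplitude is 1 inside the
#' ROI and 0 elsewhere.
#'
#' @param roi logical ROI matrix.
#' @param means per-segment phase means, degrees.
#' @param sds per-segment SDs, degrees (recycled to `length(means)`).
#' @param seed optional integer; the image is a pure function of it.
#' @return a `phase_map` (valid exactly on the ROI).
#' @export
make_phase_image <- function(roi, means, sds = 0, seed = NULL) {
  stopifnot(is.logical(roi), any(roi), length(means) >= 1)
  sds <- rep_len(sds, length(means))
  if (any(!is.finite(means)) || any(sds < 0)) {
    stop_rnvg("segment means must be finite and SDs >= 0",
              class = "rnvg_validation_error")
  }
  sec <- roi_sectors(roi, length(means))
  vals <- with_seed_if(seed, {
    rnorm(nrow(sec$idx), mean = means[sec$sector], sd = sds[sec$sector])
  })
  vals <- pmin(pmax(vals, 0), 360 - 1e-9)
  phase <- matrix(NA_real_, nrow(roi), ncol(roi))
  phase[sec$idx] <- vals
  amp <- matrix(0, nrow(roi), ncol(roi))
  amp[roi] <- 1
  phase_map(phase, amp, roi)
}

#' Preset simulated phase patterns
#'
#' Canonical contraction patterns on an 8-sector LV:
#' \describe{
#'   \item{normal}{all sectors share a common mean with small SD —
#'     synchronous contraction.}
#'   \item{mi}{one contiguous sector's mean shifted 60 degrees late, as in
#'     an apical infarct.}
#'   \item{lbbb}{sector means rising linearly by 45 degrees across the
#'     ventricle — the gradual activation delay of left bundle branch
#'     block.}
#'   \item{aneurysm}{two sector blocks with means 150 degrees apart — two
#'     regions contracting at distinctly different times.}
#' }
#' The common baseline is mean 140 degrees, SD 7.5 degrees per sector,
#' chosen so the normal preset's synchrony (~0.991) and phase SD (~7.5
#' degrees) sit near values typical of stable patients.
#'
#' @param name one of `"normal"`, `"mi"`, `"lbbb"`, `"aneurysm"`.
#' @param roi logical ROI matrix.
#' @param seed optional integer seed.
#' @param base_mean,base_sd baseline sector mean/SD in degrees.
#' @return a `phase_map`.
#' @export
preset_phase_image <- function(name = c("normal", "mi", "lbbb", "aneurysm"),
                               roi, seed = NULL,
                               base_mean = 140, base_sd = 7.5) {
  name <- match.arg(name)
  n <- 8
  means <- switch(name,
    normal   = rep(base_mean, n),
    mi       = { m <- rep(base_mean, n); m[5] <- base_mean + 60; m },
    lbbb     = base_mean + seq(0, 45, length.out = n),
    aneurysm = base_mean + c(rep(0, 4), rep(150, 4))
  )
  make_phase_image(roi, means, sds = base_sd, seed = seed)
}

#' Simulate a gated frame stack from a phase/amplitude image
#'
#' Inverse of phase extraction: each pixel's expected time-activity curve
#' is \eqn{a_0 - A\cos(2\pi k/F - 2\pi\phi/360)}, with the mean level set
#' from the amplitude via `modulation` (\eqn{A = modulation \cdot a_0},
#' so \eqn{a_0 \ge A} and rates stay non-negative) and everything scaled
#' so the total expected study counts equal `total_counts`. Pixels
#' outside the valid region get a flat background at `bg_fraction` of
#' the mean LV level. Counts are Poisson draws, or the exact expectation
#' when `noise = "none"`.
#'
#' @param phase a `phase_map` (e.g. from [preset_phase_image()]).
#' @param roi logical ROI mask stored in the returned bundle.
#' @param F frames per cardiac cycle (default 24).
#' @param total_counts target total study counts (default 5e6, a typical
#'   clinical acquisition).
#' @param noise `"poisson"` or `"none"`.
#' @param modulation ratio A/a0 inside the ventricle, in (0, 1\].
#' @param bg_fraction background level relative to mean LV a0.
#' @param seed optional integer seed; Poisson draws are a pure function
#'   of it.
#' @param patient_id id stored in the bundle.
#' @return a `study_bundle`.
#' @export
make_gated_study <- function(phase, roi, F = 24, total_counts = 5e6,
                             noise = c("poisson", "none"), modulation = 0.5,
                             bg_fraction = 0.1, seed = NULL,
                             patient_id = "SIM") {
  noise <- match.arg(noise)
  stopifnot(inherits(phase, "phase_map"), is.logical(roi),
            all(dim(roi) == dim(phase$phase)))
  if (F < 4) stop_rnvg("F must be >= 4", class = "rnvg_validation_error")
  if (total_counts <= 0) {
    stop_rnvg("total_counts must be positive", class = "rnvg_validation_error")
  }
  if (modulation <= 0 || modulation > 1) {
    stop_rnvg("modulation must be in (0, 1]: a0 >= A is required for ",
              "non-negative count rates", class = "rnvg_validation_error")
  }
  nr <- nrow(phase$phase); nc <- ncol(phase$phase)
  A_rel <- phase$amplitude
  A_rel[!phase$valid] <- 0
  a0_rel <- A_rel / modulation
  lv_mean <- mean(a0_rel[a0_rel > 0])
  a0_rel[a0_rel == 0] <- bg_fraction * lv_mean
  s <- total_counts / (F * sum(a0_rel))

  phival <- phase$phase * pi / 180
  phival[!phase$valid] <- 0
  theta <- 2 * pi * (seq_len(F) - 1) / F
  npix <- nr * nc
  # F x npix expected-rate matrix: a0 - A cos(theta - phi), scaled
  lam <- s * (matrix(as.numeric(a0_rel), F, npix, byrow = TRUE) -
              matrix(as.numeric(A_rel), F, npix, byrow = TRUE) *
                cos(outer(theta, as.numeric(phival), "-")))
  lam <- pmax(lam, 0)
  counts <- if (noise == "poisson") {
    as.double(with_seed_if(seed, rpois(length(lam), lam)))
  } else {
    lam
  }
  study_bundle(patient_id, array(counts, dim = c(F, nr, nc)), roi)
}

#' Gated study container
#'
#' @param patient_id opaque id string.
#' @param frames numeric array of counts, dim c(F, rows, cols); frame 1
#'   at the R wave.
#' @param roi logical ROI matrix matching the frame dimensions.
#' @param meta optional list of acquisition descriptors.
#' @return object of class `study_bundle`.
#' @export
study_bundle <- function(patient_id, frames, roi, meta = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  F <- dim(frames)[1]
  if (F < 4) stop_rnvg("at least 4 frames required", class = "rnvg_validation_error")
  if (anyNA(frames) || any(frames < 0)) {
    stop_rnvg("frame counts must be non-negative", class = "rnvg_validation_error")
  }
  if (!is.logical(roi) || !all(dim(roi) == dim(frames)[2:3])) {
    stop_rnvg("ROI dimensions must match the frames", class = "rnvg_format_error")
  }
  meta$F <- F
  meta$dim <- dim(frames)[2:3]
  structure(list(patient_id = as.character(patient_id), frames = frames,
                 roi = roi, meta = meta),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("study_bundle '%s': %d frames of %d x %d, %d ROI pixels\n",
              x$patient_id, x$meta$F, x$meta$dim[1], x$meta$dim[2], sum(x$roi)))
  invisible(x)
}

#' Specification for a simulated two-group patient cohort
#'
#' Defaults calibrate each group's (ApEn, synchrony, entropy, phase SD,
#' baseline LVEF) distribution to the summary statistics of a stable
#' (n = 166) versus cardiotoxic (n = 11) breast-cancer cohort. Features
#' are drawn from a per-group multivariate normal; `rho` injects a
#' correlation between ApEn and baseline LVEF (0 by default — no
#' covariances are published — but configurable because real data
#' plainly correlate the two).
#'
#' @param n_stable,n_ctrcd group sizes.
#' @param stable_mean,stable_sd,ctrcd_mean,ctrcd_sd named numeric vectors
#'   over features `apen, synchrony, entropy, phase_sd, lvef`.
#' @param rho within-group correlation between ApEn and baseline LVEF.
#' @param visit_range total RNVG visits per patient, inclusive range
#'   (baseline plus 1-8 follow-ups).
#' @param fu_sd SD of follow-up LVEF noise, percentage points.
#' @param ctrcd_target_mean,ctrcd_target_sd distribution of the nadir
#'   LVEF a cardiotoxic patient declines to.
#' @param lvef_floor minimum baseline LVEF (post-exclusion population).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stable = 166, n_ctrcd = 11,
                        stable_mean = c(apen = 0.348, synchrony = 0.991,
                                        entropy = 0.559, phase_sd = 7.90,
                                        lvef = 73.5),
                        stable_sd   = c(apen = 0.107, synchrony = 0.004,
                                        entropy = 0.040, phase_sd = 1.96,
                                        lvef = 6.1),
                        ctrcd_mean  = c(apen = 0.418, synchrony = 0.989,
                                        entropy = 0.584, phase_sd = 8.91,
                                        lvef = 64.5),
                        ctrcd_sd    = c(apen = 0.076, synchrony = 0.004,
                                        entropy = 0.028, phase_sd = 1.78,
                                        lvef = 6.7),
                        rho = 0, visit_range = c(2, 9), fu_sd = 3,
                        ctrcd_target_mean = 45, ctrcd_target_sd = 3,
                        lvef_floor = 55, seed = NULL) {
  feats <- c("apen", "synchrony", "entropy", "phase_sd", "lvef")
  for (v in list(stable_mean, stable_sd, ctrcd_mean, ctrcd_sd)) {
    stopifnot(setequal(names(v), feats))
  }
  stopifnot(n_stable >= 1, n_ctrcd >= 1, abs(rho) < 1,
            visit_range[1] >= 2, visit_range[2] <= 9,
            visit_range[1] <= visit_range[2])
  structure(list(n_stable = n_stable, n_ctrcd = n_ctrcd,
                 stable_mean = stable_mean[feats], stable_sd = stable_sd[feats],
                 ctrcd_mean = ctrcd_mean[feats], ctrcd_sd = ctrcd_sd[feats],
                 rho = rho, visit_range = visit_range, fu_sd = fu_sd,
                 ctrcd_target_mean = ctrcd_target_mean,
                 ctrcd_target_sd = ctrcd_target_sd,
                 lvef_floor = lvef_floor, seed = seed),
            class = "cohort_spec")
}

# internal: draw n rows from N(mu, Sigma) via Cholesky
rmvn <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  z <- matrix(rnorm(n * length(mu)), n)
  sweep(z %*% L, 2, mu, "+")
}

draw_group_features <- function(n, mu, sdv, rho, lvef_floor, max_tries = 1000) {
  Sigma <- diag(sdv^2)
  dimnames(Sigma) <- list(names(mu), names(mu))
  Sigma["apen", "lvef"] <- Sigma["lvef", "apen"] <- rho * sdv["apen"] * sdv["lvef"]
  X <- rmvn(n, mu, Sigma)
  colnames(X) <- names(mu)
  ok_row <- function(x) {
    x["apen"] >= 0 && x["phase_sd"] >= 0 &&
      x["synchrony"] > 0 && x["synchrony"] <= 1 &&
      x["entropy"] >= 0 && x["entropy"] <= 1 &&
      x["lvef"] >= lvef_floor && x["lvef"] <= 100
  }
  for (i in seq_len(n)) {
    tries <- 0
    while (!ok_row(X[i, ])) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop_rnvg("could not draw an admissible feature vector in ",
                  max_tries, " attempts", class = "rnvg_simulation_error")
      }
      X[i, ] <- rmvn(1, mu, Sigma)
    }
  }
  X
}

#' Simulate a two-group patient cohort with serial LVEFs
#'
#' Draws baseline feature vectors per group from the spec's multivariate
#' normals (resampling rows that violate admissibility: probabilities in
#' \[0, 1\], LVEF at or above the baseline floor), then constructs serial
#' follow-up LVEFs so that each record's ground-truth group survives the
#' guideline labeling rule: stable patients never drop more than 10
#' points below baseline to under 50%, cardiotoxic patients decline to a
#' nadir below 50% that is more than 10 points under baseline.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `cohort_table`: columns `id`, `group`
#'   (intended), features, `lvef_baseline`, follow-ups `fu_1..fu_8`
#'   (`NA`-padded), plus derived `max_lvef_drop`, `label`, `flag` from
#'   [label_groups()].
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_if(spec$seed, {
    Xs <- draw_group_features(spec$n_stable, spec$stable_mean, spec$stable_sd,
                              spec$rho, spec$lvef_floor)
    Xc <- draw_group_features(spec$n_ctrcd, spec$ctrcd_mean, spec$ctrcd_sd,
                              spec$rho, spec$lvef_floor)
    n <- spec$n_stable + spec$n_ctrcd
    X <- rbind(Xs, Xc)
    group <- rep(c("stable", "ctrcd"), c(spec$n_stable, spec$n_ctrcd))
    fu <- matrix(NA_real_, n, 8,
                 dimnames = list(NULL, paste0("fu_", 1:8)))
    for (i in seq_len(n)) {
      n_fu <- sample(spec$visit_range[1]:spec$visit_range[2], 1) - 1L
      base <- X[i, "lvef"]
      if (group[i] == "stable") {
        tries <- 0
        repeat {
          tr <- rnorm(n_fu, base - 1.5, spec$fu_sd)
          tr <- pmin(tr, 100)
          if (!(min(tr) < 50 && base - min(tr) > 10)) break
          tries <- tries + 1
          if (tries > 1000) {
            stop_rnvg("could not draw a stable trajectory",
                      class = "rnvg_simulation_error")
          }
        }
      } else {
        cap <- min(49.5, base - 10.5)
        tries <- 0
        repeat {
          target <- rnorm(1, spec$ctrcd_target_mean, spec$ctrcd_target_sd)
          if (target > 0 && target <= cap) break
          tries <- tries + 1
          if (tries > 1000) {
            stop_rnvg("infeasible cohort spec: cardiotoxic nadir cannot be ",
                      "reached from the drawn baseline",
                      class = "rnvg_simulation_error")
          }
        }
        tr <- seq(base, target, length.out = n_fu + 1)[-1]
        if (n_fu > 1) {
          tr[-n_fu] <- tr[-n_fu] + rnorm(n_fu - 1, 0, 1)
        }
        tr[n_fu] <- target
        tr <- pmax(pmin(tr, 100), 1)
      }
      fu[i, seq_len(n_fu)] <- tr
    }
    cohort <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      group = group,
      apen = X[, "apen"], synchrony = X[, "synchrony"],
      entropy = X[, "entropy"], phase_sd = X[, "phase_sd"],
      lvef_baseline = X[, "lvef"],
      fu, row.names = NULL, check.names = FALSE
    )
    label_groups(cohort)
  })
}

#' Apply the guideline cardiotoxicity labeling rule
#'
#' A record is labeled `ctrcd` when the maximum LVEF drop from baseline
#' exceeds 10 percentage points AND the minimum follow-up LVEF is below
#' 50% — otherwise `stable`. Near-miss edge cases (drop > 10 but nadir
#' still >= 50, or nadir < 50 with drop <= 10) are labeled stable and
#' flagged.
#'
#' @param records data.frame with `lvef_baseline` and follow-up columns
#'   `fu_1..fu_k` (NA-padded).
#' @return the input with columns `max_lvef_drop`, `label` (factor
#'   stable/ctrcd) and logical `flag` added/replaced; class
#'   `cohort_table`.
#' @export
label_groups <- function(records) {
  stopifnot(is.data.frame(records), "lvef_baseline" %in% names(records))
  fu_cols <- grep("^fu_[0-9]+$", names(records), value = TRUE)
  if (!length(fu_cols)) {
    stop_rnvg("no follow-up LVEF columns (fu_*) present",
              class = "rnvg_validation_error")
  }
  fu <- as.matrix(records[fu_cols])
  if (any(rowSums(!is.na(fu)) == 0)) {
    stop_rnvg("every record needs at least one follow-up LVEF",
              class = "rnvg_validation_error")
  }
  min_fu <- apply(fu, 1, min, na.rm = TRUE)
  drop <- records$lvef_baseline - min_fu
  ctrcd <- drop > 10 & min_fu < 50
  records$max_lvef_drop <- drop
  records$label <- factor(ifelse(ctrcd, "ctrcd", "stable"),
                          levels = c("stable", "ctrcd"))
  records$flag <- (drop > 10 & min_fu >= 50) | (drop <= 10 & min_fu < 50)
  class(records) <- unique(c("cohort_table", class(records)))
  records
}
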