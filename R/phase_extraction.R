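#' First-harmonic Fourier fit of a pixel time-activity curve
#'
#' Fits the model \eqn{c_k = a_0 - A\cos(2\pi k/F - 2\pi\phi/360)} to a
#' count curve over one averaged cardiac cycle by evaluating the discrete
#' Fourier transform at the fundamental frequency. Counts are minimal
#' (end-systole) at cycle fraction \eqn{\phi/360}, so a larger phase angle
#' means later contraction. The fit is exact for pure first-harmonic
#' curves at any number of frames \eqn{F \ge 4}.
#'
#' @param curve numeric vector of counts, one value per frame, frame 1 at
#'   the R wave.
#' @param amplitude_tol amplitudes below this are treated as zero and the
#'   phase flagged invalid (a constant curve has no defined phase).
#' @return list with components `a0` (mean counts), `a1`, `b1`
#'   (cosine/sine coefficients), `amplitude` (\eqn{\ge 0}), `phase`
#'   (degrees in \[0, 360), `NA` when invalid) and `valid`.
#' @examples
#' k <- 0:23
#' fit_first_harmonic(100 - 20 * cos(2 * pi * k / 24 - pi / 2))
#' @export
fit_first_harmonic <- function(curve, amplitude_tol = 1e-9) {
  if (!is.numeric(curve) || length(curve) < 4) {
    stop_rnvg("'curve' must be a numeric vector with at least 4 frames",
              class = "rnvg_validation_error")
  }
  if (anyNA(curve) || any(!is.finite(curve))) {
    stop_rnvg("'curve' contains non-finite values", class = "rnvg_validation_error")
  }
  F <- length(curve)
  theta <- 2 * pi * (seq_len(F) - 1) / F
  a0 <- mean(curve)
  # c_k = a0 - A cos(theta_k - phi)  =>  (2/F) sum c_k cos = -A cos(phi), etc.
  a1 <- 2 / F * sum(curve * cos(theta))
  b1 <- 2 / F * sum(curve * sin(theta))
  A <- sqrt(a1^2 + b1^2)
  if (A <= amplitude_tol) {
    return(list(a0 = a0, a1 = a1, b1 = b1, amplitude = 0,
                phase = NA_real_, valid = FALSE))
  }
  phase <- (atan2(-b1, -a1) * 180 / pi) %% 360
  if (phase >= 360) phase <- 0  # fp wrap artifact at the 0/360 seam
  list(a0 = a0, a1 = a1, b1 = b1, amplitude = A, phase = phase, valid = TRUE)
}

#' Phase and amplitude images from a gated study
#'
#' Applies [fit_first_harmonic()] to every pixel's time-activity curve.
#' Pixels whose first-harmonic amplitude falls below
#' `amplitude_threshold` times the image maximum are marked invalid so
#' that noise-dominated phase values never enter downstream series.
#'
#' @param study a `study_bundle` from [read_gated_study()] or
#'   [make_gated_study()].
#' @param amplitude_threshold fraction of the maximum amplitude below
#'   which a pixel's phase is invalid (default 0.05).
#' @return a `phase_map`: list with matrices `phase` (degrees, `NA` where
#'   invalid), `amplitude`, logical `valid`, and attribute
#'   `n_invalid_roi` counting ROI pixels that failed validity.
#' @export
extract_phase_amplitude <- function(study, amplitude_threshold = 0.05) {
  stopifnot(inherits(study, "study_bundle"))
  counts <- study$frames
  F <- dim(counts)[1]
  nr <- dim(counts)[2]
  nc <- dim(counts)[3]
  theta <- 2 * pi * (seq_len(F) - 1) / F
  # columns of `mat` enumerate pixels in column-major (row fastest) order
  mat <- matrix(counts, nrow = F)
  a0 <- colMeans(mat)
  a1 <- 2 / F * colSums(mat * cos(theta))
  b1 <- 2 / F * colSums(mat * sin(theta))
  A <- sqrt(a1^2 + b1^2)
  phase <- (atan2(-b1, -a1) * 180 / pi) %% 360
  phase[phase >= 360] <- 0
  maxA <- max(A)
  valid <- A > max(amplitude_threshold * maxA, 1e-9)
  phase[!valid] <- NA_real_

  pm <- phase_map(matrix(phase, nr, nc), matrix(A, nr, nc),
                  matrix(valid, nr, nc))
  n_bad <- sum(study$roi & !pm$valid)
  if (all(!pm$valid[study$roi])) {
    stop_rnvg("all ROI pixels have amplitude below the validity threshold",
              class = "rnvg_validation_error")
  }
  attr(pm, "n_invalid_roi") <- n_bad
  pm
}

#' Construct a phase/amplitude image pair
#'
#' @param phase matrix of phase angles in degrees, `NA` where invalid.
#' @param amplitude matrix of first-harmonic amplitudes (counts).
#' @param valid logical matrix of pixel validity.
#' @return object of class `phase_map`.
#' @export
phase_map <- function(phase, amplitude, valid = !is.na(phase)) {
  stopifnot(is.matrix(phase), is.matrix(amplitude), is.matrix(valid),
            all(dim(phase) == dim(amplitude)), all(dim(phase) == dim(valid)))
  pv <- phase[valid]
  if (length(pv) && (anyNA(pv) || any(pv < 0 | pv >= 360))) {
    stop_rnvg("valid phase values must lie in [0, 360)",
              class = "rnvg_validation_error")
  }
  structure(list(phase = phase, amplitude = amplitude, valid = valid),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase_map: %d x %d, %d valid pixels\n",
              nrow(x$phase), ncol(x$phase), sum(x$valid)))
  invisible(x)
}

#' Count-based left-ventricular ejection fraction
#'
#' Standard background-corrected count-based EF:
#' \deqn{LVEF = 100 (ED_{net} - ES_{net}) / ED_{net}}
#' with \eqn{X_{net} = X - bg \cdot n_{pix,X}}. A net ES below zero is
#' clamped to zero (EF capped at 100). If net ES exceeds net ED the
#' (negative) value is returned with attribute `flagged = TRUE`.
#'
#' @param ed_counts,es_counts total ROI counts at end-diastole/end-systole.
#' @param bg_per_pixel background counts per pixel (default 0).
#' @param roi_npix_ed,roi_npix_es ROI pixel counts for the two regions.
#' @return EF in percent, with logical attribute `flagged`.
#' @examples
#' compute_lvef(1000, 500, bg_per_pixel = 2, roi_npix_ed = 50, roi_npix_es = 50)
#' @export
compute_lvef <- function(ed_counts, es_counts, bg_per_pixel = 0,
                         roi_npix_ed = 0, roi_npix_es = roi_npix_ed) {
  ed_net <- ed_counts - bg_per_pixel * roi_npix_ed
  es_net <- es_counts - bg_per_pixel * roi_npix_es
  if (!is.finite(ed_net) || ed_net <= 0) {
    stop_rnvg("net end-diastolic counts must be positive",
              class = "rnvg_validation_error")
  }
  es_net <- max(es_net, 0)
  lvef <- 100 * (ed_net - es_net) / ed_net
  attr(lvef, "flagged") <- es_net > ed_net
  lvef
}

# internal: EF straight from a study bundle; ED = frame 1 (R wave),
# ES = frame with minimal ROI counts, no background region in synthetic data
lvef_from_study <- function(study, bg_per_pixel = 0) {
  roi_idx <- which(study$roi)
  F <- dim(study$frames)[1]
  mat <- matrix(study$frames, nrow = F)
  totals <- rowSums(mat[, roi_idx, drop = FALSE])
  npix <- length(roi_idx)
  compute_lvef(totals[1], min(totals), bg_per_pixel, npix, npix)
}
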