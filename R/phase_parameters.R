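#' Serpentine (boustrophedon) pixel series from a phase image
#'
#' Builds the 1-D data series that approximate entropy operates on. Rows
#' are scanned top to bottom; the row containing the topmost ROI pixel is
#' read left to right, the next row right to left, and so on, so that
#' consecutive series elements are spatially adjacent. Pixels outside the
#' ROI, or flagged invalid in the phase map, are skipped without breaking
#' the series.
#'
#' @param phase a `phase_map`, or a plain numeric matrix of phase values.
#' @param roi logical matrix, `TRUE` inside the left-ventricle ROI.
#' @return numeric vector of phase values in serpentine order.
#' @examples
#' m <- matrix(c(10, 30, 20, 40), 2, 2)  # [[10,20],[30,40]]
#' serpentine_series(m, matrix(TRUE, 2, 2))  # 10 20 40 30
#' @export
serpentine_series <- function(phase, roi) {
  if (inherits(phase, "phase_map")) {
    mask <- roi & phase$valid
    pm <- phase$phase
  } else {
    stopifnot(is.matrix(phase))
    mask <- roi & !is.na(phase)
    pm <- phase
  }
  stopifnot(is.logical(roi), all(dim(roi) == dim(pm)))
  if (!any(roi)) {
    stop_rnvg("ROI is empty", class = "rnvg_validation_error")
  }
  if (!any(mask)) {
    stop_rnvg("no valid pixels inside the ROI", class = "rnvg_validation_error")
  }
  r0 <- min(which(rowSums(roi) > 0))  # parity anchored at topmost ROI row
  out <- vector("list", nrow(pm) - r0 + 1)
  for (r in r0:nrow(pm)) {
    cols <- which(mask[r, ])
    if (!length(cols)) next
    if ((r - r0) %% 2 == 1) cols <- rev(cols)
    out[[r - r0 + 1]] <- pm[r, cols]
  }
  as.numeric(unlist(out, use.names = FALSE))
}

#' Approximate entropy of a data series
#'
#' Regularity statistic: the negative mean log conditional probability
#' that two stretches of the series which match within tolerance `r` over
#' `m` consecutive points still match at the next point. Template
#' comparison uses the maximum (Chebyshev) componentwise difference and
#' includes the self-match, and both template lengths share the same
#' comparison index range, so the result is always non-negative. Low
#' values indicate a regular, predictable series (synchronous
#' contraction); higher values indicate irregularity.
#'
#' @param series numeric vector (phase values in degrees, in serpentine
#'   order), length `N >= m + 2`.
#' @param m template length (default 2).
#' @param r tolerance, in the units of the series — degrees of phase
#'   (default 7). The (m, r) pair must be held fixed when comparing
#'   studies: ApEn lacks relative consistency and orderings can flip as r
#'   varies (see [find_flip_points()]).
#' @return non-negative scalar.
#' @examples
#' approximate_entropy(rep(c(20, 30), 5), m = 2, r = 5)  # perfectly regular: 0
#' @export
approximate_entropy <- function(series, m = 2, r = 7) {
  if (!is.numeric(series) || anyNA(series) || any(!is.finite(series))) {
    stop_rnvg("'series' must be numeric and finite", class = "rnvg_validation_error")
  }
  m <- as.integer(m)
  if (m < 1) stop_rnvg("'m' must be >= 1", class = "rnvg_validation_error")
  if (!is.finite(r) || r <= 0) {
    stop_rnvg("'r' must be > 0", class = "rnvg_validation_error")
  }
  if (length(series) < m + 2) {
    stop_rnvg("series length must be at least m + 2",
              class = "rnvg_validation_error")
  }
  .apen_cpp(as.numeric(series), m, r)
}

#' Synchrony of contraction
#'
#' Magnitude of the amplitude-weighted mean phasor of the ROI,
#' \eqn{|\sum_j A_j e^{i\phi_j}| / \sum_j A_j}. Equals 1 when every pixel
#' contracts at the same phase and decreases toward 0 as phase dispersion
#' grows; inherently circular, so it is unaffected by where the phase
#' origin is placed.
#'
#' @param phase a `phase_map` (or numeric phase matrix, degrees).
#' @param amplitude amplitude matrix; taken from `phase` when it is a
#'   `phase_map`.
#' @param roi logical ROI matrix.
#' @return value in \[0, 1\].
#' @export
synchrony <- function(phase, amplitude = NULL, roi) {
  if (inherits(phase, "phase_map")) {
    amplitude <- amplitude %||% phase$amplitude
    mask <- roi & phase$valid
    pm <- phase$phase
  } else {
    mask <- roi & !is.na(phase)
    pm <- phase
  }
  if (!any(mask)) stop_rnvg("ROI is empty", class = "rnvg_validation_error")
  A <- amplitude[mask]
  ph <- pm[mask] * pi / 180
  tot <- sum(A)
  if (tot <= 0) {
    stop_rnvg("total ROI amplitude is zero", class = "rnvg_validation_error")
  }
  min(Mod(sum(A * exp(1i * ph))) / tot, 1)
}

#' Normalized phase-histogram entropy
#'
#' Shannon entropy of the ROI phase histogram over `bins` equal-width
#' bins on \[0, 360) degrees, normalized by `log(bins)` so the result
#' lies in \[0, 1\]: 0 when every phase falls in a single bin, 1 when the
#' histogram is exactly uniform. A measure of randomness of contraction
#' timing that ignores spatial arrangement.
#'
#' @inheritParams synchrony
#' @param bins number of histogram bins (default 64, must be >= 2).
#' @return value in \[0, 1\].
#' @export
phase_entropy <- function(phase, roi, bins = 64) {
  bins <- as.integer(bins)
  if (bins < 2) stop_rnvg("'bins' must be >= 2", class = "rnvg_validation_error")
  ph <- roi_phase_values(phase, roi)
  idx <- pmin(floor(ph / (360 / bins)), bins - 1)
  p <- tabulate(idx + 1L, nbins = bins) / length(ph)
  p <- p[p > 0]
  -sum(p * log(p)) / log(bins)
}

#' Phase standard deviation
#'
#' Unweighted sample standard deviation (denominator N - 1) of the ROI
#' phase values, in degrees. Phases are treated as linear quantities; no
#' circular wrapping is applied.
#'
#' @inheritParams synchrony
#' @return SD in degrees.
#' @export
phase_sd <- function(phase, roi) {
  ph <- roi_phase_values(phase, roi)
  if (length(ph) < 2) {
    stop_rnvg("phase SD needs at least 2 ROI pixels",
              class = "rnvg_validation_error")
  }
  sd(ph)
}

roi_phase_values <- function(phase, roi) {
  if (inherits(phase, "phase_map")) {
    mask <- roi & phase$valid
    pm <- phase$phase
  } else {
    mask <- roi & !is.na(phase)
    pm <- phase
  }
  if (!any(mask)) stop_rnvg("ROI is empty", class = "rnvg_validation_error")
  pm[mask]
}

#' All phase parameters plus LVEF for one study
#'
#' Runs phase/amplitude extraction and computes approximate entropy (over
#' the serpentine series), synchrony, normalized histogram entropy, phase
#' SD and count-based LVEF. Deterministic given its inputs.
#'
#' @param study a `study_bundle`.
#' @param m,r approximate-entropy parameters; defaults m = 2, r = 7
#'   degrees, the operating point selected by the simulation-based
#'   optimization (see [sweep_apen()]).
#' @param bins histogram bins for entropy.
#' @param amplitude_threshold see [extract_phase_amplitude()].
#' @return object of class `phase_features`: named list with `apen`,
#'   `synchrony`, `entropy`, `phase_sd`, `lvef`.
#' @export
compute_features <- function(study, m = 2, r = 7, bins = 64,
                             amplitude_threshold = 0.05) {
  pm <- extract_phase_amplitude(study, amplitude_threshold)
  series <- serpentine_series(pm, study$roi)
  structure(list(
    apen      = approximate_entropy(series, m = m, r = r),
    synchrony = synchrony(pm, roi = study$roi),
    entropy   = phase_entropy(pm, study$roi, bins = bins),
    phase_sd  = phase_sd(pm, study$roi),
    lvef      = as.numeric(lvef_from_study(study))
  ), class = "phase_features")
}

#' @export
print.phase_features <- function(x, ...) {
  cat(sprintf(
    "phase features: ApEn %.4f | synchrony %.4f | entropy %.4f | phase SD %.2f deg | LVEF %.1f%%\n",
    x$apen, x$synchrony, x$entropy, x$phase_sd, x$lvef))
  invisible(x)
}
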