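#' Sweep approximate entropy over a grid of (m, r)
#'
#' Evaluates ApEn for each image's serpentine series at every
#' combination of template length and tolerance. Deterministic: the
#' grid depends only on the input images.
#'
#' @param images named list; each element either a numeric series, or a
#'   list with components `phase` (a `phase_map` or matrix) and `roi`.
#' @param m_values integer template lengths (default 1:5).
#' @param r_values tolerances in degrees (default 0.25 to 21 by 0.25,
#'   the range probed when selecting the operating point).
#' @return long-format `data.frame` of class `apen_sweep` with columns
#'   `image_id`, `m`, `r`, `apen`.
#' @export
sweep_apen <- function(images, m_values = 1:5,
                       r_values = seq(0.25, 21, by = 0.25)) {
  stopifnot(length(images) >= 1, length(m_values) >= 1, length(r_values) >= 1)
  ids <- names(images) %||% as.character(seq_along(images))
  if (is.null(names(images))) names(images) <- ids
  series <- lapply(images, as_phase_series)
  grid <- expand.grid(image_id = ids, m = as.integer(m_values), r = r_values,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$apen <- mapply(function(id, m, r) {
    approximate_entropy(series[[id]], m = m, r = r)
  }, grid$image_id, grid$m, grid$r)
  class(grid) <- c("apen_sweep", "data.frame")
  grid
}

as_phase_series <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x) && !is.null(x$phase) && !is.null(x$roi)) {
    return(serpentine_series(x$phase, x$roi))
  }
  stop_rnvg("each image must be a numeric series or list(phase=, roi=)",
            class = "rnvg_validation_error")
}

#' Locate flip points between a normal and an abnormal series
#'
#' ApEn lacks relative consistency: as the tolerance r grows, the
#' ordering of two series can reverse. The tolerance where the normal
#' and abnormal ApEn coincide — where ApEn cannot discriminate at all —
#' is the flip point. Every sign change of
#' d(r) = ApEn(abnormal) - ApEn(normal) across consecutive grid points
#' is reported with a linearly interpolated crossing; an exact zero at a
#' grid point is reported with a zero-width bracket.
#'
#' @param normal,abnormal numeric phase series (serpentine order).
#' @param m template length.
#' @param r_grid tolerance grid, strictly increasing.
#' @return `data.frame` with columns `r_star`, `r_lo`, `r_hi`,
#'   `sign_before`, `sign_after`; attribute `degenerate` is `TRUE` when
#'   d is identically zero (identical series), and attribute `d` holds
#'   the difference profile.
#' @export
find_flip_points <- function(normal, abnormal, m = 2,
                             r_grid = seq(0.25, 21, by = 0.25)) {
  if (!length(r_grid)) {
    stop_rnvg("r_grid is empty", class = "rnvg_validation_error")
  }
  stopifnot(!is.unsorted(r_grid, strictly = TRUE))
  d <- vapply(r_grid, function(r) {
    approximate_entropy(abnormal, m = m, r = r) -
      approximate_entropy(normal, m = m, r = r)
  }, numeric(1))
  out <- data.frame(r_star = numeric(0), r_lo = numeric(0), r_hi = numeric(0),
                    sign_before = numeric(0), sign_after = numeric(0))
  if (all(d == 0)) {
    attr(out, "degenerate") <- TRUE
    attr(out, "d") <- d
    return(out)
  }
  s <- sign(d)
  rows <- list()
  for (i in seq_along(r_grid)) {
    if (d[i] == 0) {
      before <- if (i > 1) s[i - 1] else 0
      after <- if (i < length(d)) s[i + 1] else 0
      rows[[length(rows) + 1]] <- data.frame(
        r_star = r_grid[i], r_lo = r_grid[i], r_hi = r_grid[i],
        sign_before = before, sign_after = after)
    } else if (i < length(d) && d[i] * d[i + 1] < 0) {
      r_star <- r_grid[i] + (r_grid[i + 1] - r_grid[i]) *
        abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
      rows[[length(rows) + 1]] <- data.frame(
        r_star = r_star, r_lo = r_grid[i], r_hi = r_grid[i + 1],
        sign_before = s[i], sign_after = s[i + 1])
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  attr(out, "degenerate") <- FALSE
  attr(out, "d") <- d
  out
}

#' Recommend an operating tolerance clear of all flip points
#'
#' Advisory rule: over one or many normal/abnormal pairs, pick the grid
#' tolerance that maximizes the distance to the union of observed flip
#' intervals. A sound operating point must sit well away from every
#' flip, since near a flip ApEn cannot separate normal from abnormal and
#' the ordering of the two is unstable.
#'
#' @param flip_points a `data.frame` from [find_flip_points()], or a
#'   list of them (one per image pair), rbind-ed internally.
#' @param r_grid candidate tolerances.
#' @param margin minimum acceptable distance (degrees); a warning is
#'   recorded when no candidate achieves it.
#' @return list with `r` (recommended tolerance), `distance` (its
#'   clearance from the nearest flip interval, `Inf` when no flips),
#'   `flips` (combined flip table) and `warnings` (character).
#' @export
recommend_r <- function(flip_points, r_grid = seq(0.25, 21, by = 0.25),
                        margin = 1) {
  if (is.data.frame(flip_points)) flip_points <- list(flip_points)
  if (!length(flip_points)) {
    stop_rnvg("at least one analyzed pair is required",
              class = "rnvg_validation_error")
  }
  flips <- do.call(rbind, flip_points)
  warnings <- character(0)
  if (is.null(flips) || nrow(flips) == 0) {
    warnings <- c(warnings,
                  "no flip points observed on the grid; recommendation is the grid midpoint")
    return(list(r = r_grid[ceiling(length(r_grid) / 2)], distance = Inf,
                flips = flips, warnings = warnings))
  }
  dist_to <- vapply(r_grid, function(r) {
    min(pmax(pmax(flips$r_lo - r, r - flips$r_hi), 0))
  }, numeric(1))
  best <- which.max(dist_to)
  if (dist_to[best] < margin) {
    warnings <- c(warnings, sprintf(
      "no tolerance on the grid is more than %.3g degrees from every flip interval",
      margin))
  }
  list(r = r_grid[best], distance = dist_to[best], flips = flips,
       warnings = warnings)
}

#' Relative-consistency check over a sweep
#'
#' Flags image pairs whose ApEn ordering reverses anywhere on the (m, r)
#' grid — the practical reason (m, r) must be fixed before comparing
#' studies.
#'
#' @param sweep an `apen_sweep`.
#' @return character vector of warning lines (empty when no pair swaps).
#' @export
consistency_warnings <- function(sweep) {
  stopifnot(inherits(sweep, "apen_sweep"))
  ids <- unique(sweep$image_id)
  out <- character(0)
  if (length(ids) < 2) return(out)
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1)) {
      sa <- sweep[sweep$image_id == ids[a], ]
      sb <- sweep[sweep$image_id == ids[b], ]
      key <- function(x) paste(x$m, x$r)
      sb <- sb[match(key(sa), key(sb)), ]
      d <- sa$apen - sb$apen
      if (any(d > 0) && any(d < 0)) {
        out <- c(out, sprintf(
          "relative consistency violated: ApEn ordering of '%s' and '%s' depends on (m, r)",
          ids[a], ids[b]))
      }
    }
  }
  out
}
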