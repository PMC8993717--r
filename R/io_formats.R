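#' Read a gated blood-pool study from disk
#'
#' The supported on-disk layout is a frame directory: one headerless CSV
#' count matrix per frame named `frame_000.csv`, `frame_001.csv`, ...,
#' a `mask.csv` of 0/1 for the LV ROI, and an optional `meta.dcf` with
#' `patient_id`. Frame order is preserved as stored (frame 1 = R wave).
#' Multi-frame DICOM is not supported by this build: no DICOM reader is
#' available in the target R environment, and the frame directory is the
#' portable interchange format.
#'
#' @param path directory containing the study.
#' @param format_hint `"framedir"` (default) or `"dicom"` (errors).
#' @return a `study_bundle`.
#' @export
read_gated_study <- function(path, format_hint = c("framedir", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "dicom") {
    stop_rnvg("DICOM input is not supported by this build; convert the ",
              "study to a CSV frame directory (frame_000.csv ... + mask.csv)",
              class = "rnvg_format_error")
  }
  if (!dir.exists(path)) {
    stop_rnvg("study directory not found: ", path, class = "rnvg_io_error")
  }
  frame_files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.csv$",
                                 full.names = TRUE))
  if (length(frame_files) == 0) {
    stop_rnvg("no frame_*.csv files in ", path, class = "rnvg_format_error")
  }
  if (length(frame_files) < 4) {
    stop_rnvg("at least 4 frames are required, found ", length(frame_files),
              class = "rnvg_validation_error")
  }
  frames <- lapply(frame_files, read_csv_matrix)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_rnvg("frames have non-uniform shapes", class = "rnvg_format_error")
  }
  counts <- array(0, dim = c(length(frames), dims[1, 1], dims[2, 1]))
  for (k in seq_along(frames)) {
    if (anyNA(frames[[k]]) || any(frames[[k]] < 0)) {
      stop_rnvg("frame ", k, " contains negative or missing counts",
                class = "rnvg_format_error")
    }
    counts[k, , ] <- frames[[k]]
  }
  mask_file <- file.path(path, "mask.csv")
  if (!file.exists(mask_file)) {
    stop_rnvg("mask.csv missing from ", path, class = "rnvg_format_error")
  }
  roi <- read_csv_matrix(mask_file) != 0
  meta_file <- file.path(path, "meta.dcf")
  pid <- basename(path)
  if (file.exists(meta_file)) {
    meta <- read.dcf(meta_file)
    if ("patient_id" %in% colnames(meta)) pid <- meta[1, "patient_id"]
  }
  study_bundle(pid, counts, roi)
}

#' Write a gated study as a CSV frame directory
#'
#' @param study a `study_bundle`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_gated_study <- function(study, path) {
  stopifnot(inherits(study, "study_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    stop_rnvg("cannot create ", path, class = "rnvg_io_error")
  }
  F <- study$meta$F
  for (k in seq_len(F)) {
    write_csv_matrix(study$frames[k, , ],
                     file.path(path, sprintf("frame_%03d.csv", k - 1)))
  }
  write_csv_matrix(study$roi * 1L, file.path(path, "mask.csv"))
  write.dcf(data.frame(patient_id = study$patient_id, F = F),
            file.path(path, "meta.dcf"))
  invisible(path)
}

read_csv_matrix <- function(file) {
  m <- as.matrix(read.csv(file, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

write_csv_matrix <- function(m, file) {
  # full double precision so float round-trips hold to <1e-9
  txt <- apply(m, 1, function(row) paste(formatC(row, format = "g", digits = 17),
                                         collapse = ","))
  writeLines(txt, file)
}

#' Write / read a per-patient feature table
#'
#' One row per patient: id, the four phase parameters, baseline LVEF,
#' maximum LVEF drop and group label, written as CSV with full float
#' precision so a write-read cycle is lossless well beyond 1e-6.
#'
#' @param cohort a `cohort_table` (or any data.frame with the feature
#'   columns).
#' @param path output CSV file.
#' @return `path` invisibly; `read_feature_table` returns a data.frame.
#' @export
write_feature_table <- function(cohort, path) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_rnvg("cohort must be a non-empty data.frame",
              class = "rnvg_validation_error")
  }
  cols <- c("id", "apen", "synchrony", "entropy", "phase_sd",
            "lvef_baseline", "max_lvef_drop", "label")
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop_rnvg("cohort lacks columns: ", paste(missing, collapse = ", "),
              class = "rnvg_validation_error")
  }
  write_table_precise(cohort[cols], path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop_rnvg("file not found: ", path, class = "rnvg_io_error")
  }
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(out)) {
    out$label <- factor(out$label, levels = c("stable", "ctrcd"))
  }
  out
}

#' Write / read a full cohort table (features plus serial LVEFs)
#'
#' @param cohort a `cohort_table` from [make_cohort()].
#' @param path CSV file.
#' @export
write_cohort_table <- function(cohort, path) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_rnvg("cohort must be a non-empty data.frame",
              class = "rnvg_validation_error")
  }
  write_table_precise(cohort, path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    stop_rnvg("file not found: ", path, class = "rnvg_io_error")
  }
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(out)) {
    out$label <- factor(out$label, levels = c("stable", "ctrcd"))
  }
  class(out) <- unique(c("cohort_table", class(out)))
  out
}

write_table_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
      df[[j]][df[[j]] == "NA"] <- NA
    }
  }
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop_rnvg("could not write ", path, class = "rnvg_io_error")
  }
  invisible(path)
}

#' Write / read a phase/amplitude image pair as CSV matrices
#'
#' Writes `phase.csv` (NA where invalid), `amplitude.csv` and
#' `valid.csv` into a directory.
#'
#' @param pm a `phase_map`.
#' @param path directory.
#' @export
write_phase_map <- function(pm, path) {
  stopifnot(inherits(pm, "phase_map"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ph <- pm$phase
  txt <- apply(ph, 1, function(row) {
    v <- formatC(row, format = "g", digits = 17)
    v[is.na(row)] <- "NA"
    paste(v, collapse = ",")
  })
  writeLines(txt, file.path(path, "phase.csv"))
  write_csv_matrix(pm$amplitude, file.path(path, "amplitude.csv"))
  write_csv_matrix(pm$valid * 1L, file.path(path, "valid.csv"))
  invisible(path)
}

#' @rdname write_phase_map
#' @export
read_phase_map <- function(path) {
  ph <- as.matrix(read.csv(file.path(path, "phase.csv"), header = FALSE))
  dimnames(ph) <- NULL
  storage.mode(ph) <- "double"
  amp <- read_csv_matrix(file.path(path, "amplitude.csv"))
  valid <- read_csv_matrix(file.path(path, "valid.csv")) != 0
  phase_map(ph, amp, valid)
}

#' Read a key-value configuration file
#'
#' DCF format (`key: value` lines). Recognized numeric keys (`m`, `r`,
#' `bins`, `seed`, `F`, `total_counts`, `amplitude_threshold`, `folds`,
#' `repeats`, `ntree`, `n_stable`, `n_ctrcd`) are coerced; everything
#' else stays character. Command-line flags override config values.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_rnvg("config file not found: ", path, class = "rnvg_io_error")
  }
  m <- read.dcf(path)
  out <- as.list(m[1, ])
  numeric_keys <- c("m", "r", "bins", "seed", "F", "total_counts",
                    "amplitude_threshold", "folds", "repeats", "ntree",
                    "n_stable", "n_ctrcd")
  for (k in intersect(names(out), numeric_keys)) {
    out[[k]] <- as.numeric(out[[k]])
  }
  out
}
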