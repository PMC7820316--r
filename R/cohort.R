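# Per-patient aggregation and the analysis table -------------------------

#' Collapse two eyes into the per-patient variables
#'
#' The four patient-level variables take the *worse* eye in each sense:
#' `SNR_min` is the SNR of the eye with the lesser amplitude (the smaller
#' eye SNR), `Lat_max` the latency of the eye with the greatest delay, and
#' `b_max` / `N_max` the larger of the two per-eye means.
#'
#' @param eye_a,eye_b [eye_features()] objects for the two eyes (either
#'   may be `NULL` only when `allow_single_eye = TRUE`).
#' @param allow_single_eye fall back to the available eye, with a warning
#'   and `single_eye = TRUE` in the result.
#' @return one-row `data.frame` with `patient_id`, `snr_min`,
#'   `lat_max_ms`, `bmax_ms`, `nmax`, `single_eye`.
#' @export
patient_features <- function(eye_a, eye_b, allow_single_eye = FALSE) {
  eyes <- Filter(Negate(is.null), list(eye_a, eye_b))
  if (length(eyes) == 0) stop("no eyes supplied")
  if (length(eyes) == 1) {
    if (!allow_single_eye)
      stop("one eye missing; pass allow_single_eye = TRUE to use the ",
           "available eye")
    warning("patient has a single eye: per-patient variables use that eye")
  }
  pid <- unique(na.omit(vapply(eyes, function(e) e$meta$patient_id,
                               character(1))))
  data.frame(
    patient_id = if (length(pid)) pid[1] else NA_character_,
    snr_min = min(vapply(eyes, `[[`, numeric(1), "snr")),
    lat_max_ms = max(vapply(eyes, `[[`, numeric(1), "latency_ms")),
    bmax_ms = max(vapply(eyes, `[[`, numeric(1), "bmax_ms")),
    nmax = max(vapply(eyes, `[[`, numeric(1), "nmax")),
    single_eye = length(eyes) == 1,
    stringsAsFactors = FALSE
  )
}

#' Assemble the patient-level analysis table
#'
#' Joins per-patient features with group labels and event data, one row
#' per patient, ordered by `patient_id`.
#'
#' @param features `data.frame` of stacked [patient_features()] rows.
#' @param labels `data.frame` with `patient_id`, `group`.
#' @param events `data.frame` with `patient_id`, `time_months`, `event`.
#' @return `data.frame` with columns `patient_id`, `snr_min`,
#'   `lat_max_ms`, `bmax_ms`, `nmax`, `group`, `time_months`, `event`.
#' @export
assemble_table <- function(features, labels, events) {
  cols <- c("patient_id", "snr_min", "lat_max_ms", "bmax_ms", "nmax")
  if (nrow(features) == 0)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 8)),
      c(cols, "group", "time_months", "event")))
  bad <- c(setdiff(features$patient_id, labels$patient_id),
           setdiff(features$patient_id, events$patient_id),
           setdiff(labels$patient_id, features$patient_id),
           setdiff(events$patient_id, features$patient_id))
  if (length(bad))
    stop("patient_id mismatch across inputs: ",
         paste(unique(bad), collapse = ", "))
  out <- merge(features[, cols], labels[, c("patient_id", "group")],
               by = "patient_id")
  out <- merge(out, events[, c("patient_id", "time_months", "event")],
               by = "patient_id")
  out[order(out$patient_id), , drop = FALSE]
}

#' Extract the full patient table from a generated cohort
#'
#' Convenience wrapper running [eye_features()] on both eyes of every
#' patient and assembling the analysis table.
#'
#' @param cohort output of [generate_cohort()].
#' @param normdb a [normative_db()] (or `NULL` to skip latency).
#' @inheritParams eye_features
#' @return list with `patients` (the analysis table) and `eyes` (per-eye
#'   feature `data.frame`).
#' @export
cohort_features <- function(cohort, normdb = NULL, windows = window_spec(),
                            scales = cwt_default_scales(), max_lag = 50) {
  eye_rows <- list()
  pat_rows <- list()
  for (pid in names(cohort$records)) {
    fa <- eye_features(cohort$records[[pid]]$OD, normdb, windows, scales,
                       max_lag)
    fb <- eye_features(cohort$records[[pid]]$OS, normdb, windows, scales,
                       max_lag)
    eye_rows[[length(eye_rows) + 1L]] <- data.frame(
      patient_id = pid, eye = c("OD", "OS"),
      snr = c(fa$snr, fb$snr),
      latency_ms = c(fa$latency_ms, fb$latency_ms),
      bmax_ms = c(fa$bmax_ms, fb$bmax_ms),
      nmax = c(fa$nmax, fb$nmax), stringsAsFactors = FALSE)
    pat_rows[[length(pat_rows) + 1L]] <- patient_features(fa, fb)
  }
  eyes <- do.call(rbind, eye_rows)
  feats <- do.call(rbind, pat_rows)
  list(patients = assemble_table(feats, cohort$labels, cohort$events),
       eyes = eyes)
}

#' Write / read the patient-level CSV
#'
#' Plain-text round-trip of the analysis table
#' (`patient_id,snr_min,lat_max_ms,bmax_ms,nmax,group,time_months,event`),
#' preserving full double precision.
#'
#' @param patients the analysis table.
#' @param path file path.
#' @return `read_patient_table` returns the table; `write_patient_table`
#'   its path, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(format(patients, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patient_table
#' @export
read_patient_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in c("snr_min", "lat_max_ms", "bmax_ms", "nmax", "time_months"))
    if (v %in% names(out)) out[[v]] <- as.numeric(out[[v]])
  out
}
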