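#' Write / read the marker CSV dialect
#'
#' Delimited text with header `time,LASIS_x,...,RPSIS_z`; positions in
#' meters, axes x/y/z = vertical/mediolateral/anteroposterior, nominally
#' 250 Hz. Reading validates the header, monotone timestamps and the
#' sampling rate, and interpolates onto an exactly uniform grid when the
#' timestamp jitter is below 1% of the sampling interval (an error
#' otherwise: gaps are an ingest error, not a runtime state).
#'
#' @param markers a `marker_set`.
#' @param path file path.
#' @return `write_marker_csv`: the path, invisibly. `read_marker_csv`: a
#'   `marker_set`.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  df <- cbind(time = series_time(markers), markers$data)
  write_uniform_csv(df, path)
}

#' @rdname write_marker_csv
#' @param expected_rate nominal rate to validate against (Hz), or `NULL`.
#' @export
read_marker_csv <- function(path, expected_rate = 250) {
  cols <- as.vector(t(outer(marker_labels, c("x", "y", "z"), paste, sep = "_")))
  out <- read_uniform_csv(path, cols, expected_rate)
  mk <- uniform_series(out$data, rate = out$rate, start = out$start)
  mk$labels <- marker_labels
  class(mk) <- c("marker_set", "uniform_series")
  mk
}

#' Write / read the smartphone CSV dialect
#'
#' Delimited text with header `time,ax,ay,az,roll,pitch,azimuth`
#' (acceleration in m/s^2, orientation in degrees, nominally 100 Hz),
#' mirroring a MATLAB-Mobile-style sensor export. Validation as in
#' [read_marker_csv()]; the rate must be within 1% of nominal.
#'
#' @param phone a `phone_recording`.
#' @param path file path.
#' @return `write_phone_csv`: the path, invisibly. `read_phone_csv`: a
#'   `phone_recording`.
#' @export
write_phone_csv <- function(phone, path) {
  stopifnot(inherits(phone, "phone_recording"))
  df <- cbind(time = series_time(phone), phone$data)
  write_uniform_csv(df, path)
}

#' @rdname write_phone_csv
#' @param expected_rate nominal rate (Hz), or `NULL` to skip the check.
#' @export
read_phone_csv <- function(path, expected_rate = 100) {
  cols <- c("ax", "ay", "az", "roll", "pitch", "azimuth")
  out <- read_uniform_csv(path, cols, expected_rate)
  ph <- uniform_series(out$data, rate = out$rate, start = out$start)
  class(ph) <- c("phone_recording", "uniform_series")
  ph
}

write_uniform_csv <- function(df, path) {
  df[] <- lapply(df, function(col) sprintf("%.10g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_uniform_csv <- function(path, required_cols, expected_rate) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("time", required_cols), names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")))
  t <- df$time
  n <- length(t)
  if (n < 2L) stop(sprintf("%s: need at least 2 samples", basename(path)))
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("%s: non-monotone time at row %d", basename(path), bad[1] + 1L))
  dt <- (t[n] - t[1]) / (n - 1L)
  rate <- 1 / dt
  if (!is.null(expected_rate) && abs(rate - expected_rate) / expected_rate > 0.01)
    stop(sprintf("%s: sampling rate %.2f Hz deviates more than 1%% from nominal %g Hz",
                 basename(path), rate, expected_rate))
  grid <- t[1] + (seq_len(n) - 1L) * dt
  jitter <- max(abs(t - grid)) / dt
  data <- df[required_cols]
  if (jitter > 0) {
    if (jitter > 0.01)
      stop(sprintf("%s: timestamp jitter %.1f%% of the sampling interval exceeds 1%%",
                   basename(path), 100 * jitter))
    data[] <- lapply(data, function(col) stats::approx(t, col, xout = grid)$y)
  }
  list(data = data, rate = rate, start = t[1])
}

#' Ground-truth sidecar for a simulated recording
#'
#' JSON with the true repetition start/peak/end times, true peak angles,
#' depth and pace of one simulated recording; written next to the rendered
#' CSVs so recovery can be checked without re-simulating.
#'
#' @param pose a `pose_trajectory`.
#' @param path file path.
#' @export
write_truth_json <- function(pose, path) {
  stopifnot(inherits(pose, "pose_trajectory"))
  jsonlite::write_json(
    list(task = pose$params$task, events = pose$events,
         true_peaks = as.list(pose$true_peaks),
         depth = pose$params$depth,
         rep_duration = pose$params$rep_duration,
         ml_accel_target = pose$params$ml_accel_target),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulated cohort as fixture files
#'
#' One marker CSV, one phone CSV and one ground-truth JSON per recording,
#' named `<participant>_<task>_{markers,phone,truth}.*`. Deterministic file
#' content under a fixed cohort seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pelvic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$records)) {
    rec <- cohort$records[[id]]
    write_marker_csv(rec$markers, file.path(dir, paste0(id, "_markers.csv")))
    write_phone_csv(rec$phone, file.path(dir, paste0(id, "_phone.csv")))
    write_truth_json(rec$pose, file.path(dir, paste0(id, "_truth.json")))
  }
  invisible(dir)
}
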