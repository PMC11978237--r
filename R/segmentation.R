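#' Segmentation parameters
#'
#' Constants of the automatic repetition detector. The reference analysis
#' identified repetition events visually; this detector replaces that step
#' with a threshold-plus-hysteresis automaton on the vertical-displacement
#' channel, and every constant is a parameter with documented defaults.
#'
#' @param enter_threshold displacement below baseline (m) that opens a
#'   candidate repetition (default 10 mm).
#' @param exit_fraction the hysteresis exit threshold as a fraction of
#'   `enter_threshold` (default 0.5); the start/end are the outermost
#'   crossings of the exit threshold, refined by linear interpolation.
#' @param min_duration minimum repetition duration, s (default 1).
#' @param min_depth minimum repetition depth, m (default 30 mm).
#' @param plateau_tolerance displacement tolerance (m) used to call a
#'   bottom plateau (default 2 mm).
#' @param plateau_min minimum plateau dwell, s (default 0.2); when the
#'   minimum sits on a plateau at least this long, the peak is the temporal
#'   midpoint of the plateau.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(enter_threshold = 0.010, exit_fraction = 0.5,
                                min_duration = 1, min_depth = 0.030,
                                plateau_tolerance = 0.002, plateau_min = 0.2) {
  if (enter_threshold <= 0 || min_depth <= 0) stop("thresholds must be positive")
  if (exit_fraction <= 0 || exit_fraction > 1)
    stop("`exit_fraction` must be in (0, 1]")
  structure(as.list(environment()), class = "segmentation_params")
}

#' Find the quiet-standing baseline
#'
#' Scans the pre-task quiet span for the `stability_window` whose three angle
#' channels have the smallest summed rolling variance, and returns the window
#' centre and the window means of every channel - the baseline the angle
#' outcomes are referenced to.
#'
#' @param kinematics a `pelvic_kinematics` series.
#' @param quiet_duration length of the pre-task quiet span, s.
#' @param stability_window width of the stability window, s (default 0.5).
#' @param var_ceiling maximum admissible summed angle variance (deg^2) of the
#'   chosen window; above it the baseline is declared unstable.
#' @return list with `index`, `time` (s) and `values` (named channel means).
#' @export
find_baseline <- function(kinematics, quiet_duration = 5,
                          stability_window = 0.5, var_ceiling = 4) {
  stopifnot(inherits(kinematics, "pelvic_kinematics"))
  rate <- kinematics$rate
  n_quiet <- floor(quiet_duration * rate)
  if (n_quiet > n_samples(kinematics))
    stop(sprintf("recording shorter than the %g s quiet span", quiet_duration))
  w <- max(2L, round(stability_window * rate))
  if (w > n_quiet) stop("stability window longer than the quiet span")
  total_var <- numeric(n_quiet - w + 1L)
  for (ch in c("transverse", "frontal", "sagittal")) {
    x <- kinematics$data[[ch]][seq_len(n_quiet)]
    total_var <- total_var + rolling_var(x, w)
  }
  best <- which.min(total_var)
  if (total_var[best] > var_ceiling)
    stop(sprintf("unstable baseline: best window variance %.3g deg^2 exceeds ceiling %.3g",
                 total_var[best], var_ceiling))
  idx <- best:(best + w - 1L)
  values <- vapply(kinematics$data, function(col) mean(col[idx]), numeric(1))
  list(index = best + (w - 1L) %/% 2L,
       time = (best + (w - 1L) %/% 2L - 1L) / rate,
       values = values)
}

# Rolling sample variance of x over windows of w samples (one value per
# window start), computed from cumulative sums.
rolling_var <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1L)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  (s2 - s^2 / w) / (w - 1)
}

#' Detect repetitions in a vertical-displacement channel
#'
#' Candidate repetitions are maximal spans where the displacement is more
#' than `enter_threshold` below baseline; each span is extended outward to
#' the crossings of the exit threshold (hysteresis), with sub-sample crossing
#' times by linear interpolation. Spans shorter than `min_duration` or
#' shallower than `min_depth` are discarded. The peak is the sample of
#' minimum displacement or, when the minimum sits on a plateau (within
#' `plateau_tolerance` for at least `plateau_min` seconds), the temporal
#' midpoint of the plateau. Because the start/end crossings lie inside the
#' true movement span, detected durations are systematically slightly shorter
#' than true durations.
#'
#' @param displacement numeric vertical-displacement vector, m.
#' @param rate sampling rate, Hz.
#' @param baseline_value baseline displacement value, m.
#' @param params a [segmentation_params()].
#' @param expected_reps optional expected repetition count; a mismatch
#'   attaches a warning flag (see [validate_marks()] for strict handling).
#' @param search_start ignore samples before this time (s); the study runner
#'   sets it to the end of the quiet-standing span, where the protocol says
#'   the first repetition can begin, so that low-frequency distortion of the
#'   integrated smartphone displacement spreading backward from the first
#'   repetition is never read as a movement.
#' @return an object of class `repetition_marks`: list with `reps` (data.frame
#'   start_time, peak_time, end_time, start_index, peak_index, end_index,
#'   depth, plateau), `rate`, `expected_reps`, `count_mismatch`.
#' @export
detect_repetitions <- function(displacement, rate, baseline_value = 0,
                               params = segmentation_params(),
                               expected_reps = NULL, search_start = 0) {
  stopifnot(inherits(params, "segmentation_params"))
  offset <- 0L
  if (search_start > 0) {
    offset <- min(length(displacement) - 2L, floor(search_start * rate))
    displacement <- displacement[(offset + 1L):length(displacement)]
  }
  rel <- displacement - baseline_value
  n <- length(rel)
  t <- (seq_len(n) - 1L + offset) / rate
  enter <- -params$enter_threshold
  exit <- enter * params$exit_fraction

  below_enter <- rel < enter
  reps <- list()
  i <- 1L
  while (i <= n) {
    if (!below_enter[i]) { i <- i + 1L; next }
    run_end <- i
    while (run_end < n && below_enter[run_end + 1L]) run_end <- run_end + 1L
    # extend to the outermost exit-threshold crossings
    s <- i
    while (s > 1L && rel[s - 1L] < exit) s <- s - 1L
    e <- run_end
    while (e < n && rel[e + 1L] < exit) e <- e + 1L
    start_time <- if (s > 1L) {
      interp_crossing(t[s - 1L], t[s], rel[s - 1L], rel[s], exit)
    } else t[1L]
    end_time <- if (e < n) {
      interp_crossing(t[e], t[e + 1L], rel[e], rel[e + 1L], exit)
    } else t[n]
    span <- s:e
    min_idx <- span[which.min(rel[span])]
    depth <- -min(rel[span])
    # plateau: contiguous run around the minimum within tolerance
    tol <- min(rel[span]) + params$plateau_tolerance
    pl_lo <- min_idx
    while (pl_lo > s && rel[pl_lo - 1L] <= tol) pl_lo <- pl_lo - 1L
    pl_hi <- min_idx
    while (pl_hi < e && rel[pl_hi + 1L] <= tol) pl_hi <- pl_hi + 1L
    plateau <- (t[pl_hi] - t[pl_lo]) >= params$plateau_min
    peak_time <- if (plateau) (t[pl_lo] + t[pl_hi]) / 2 else t[min_idx]
    peak_index <- which.min(abs(t - peak_time))
    reps[[length(reps) + 1L]] <- data.frame(
      start_time = start_time, peak_time = peak_time, end_time = end_time,
      start_index = s + offset, peak_index = peak_index + offset,
      end_index = e + offset, depth = depth, plateau = plateau
    )
    i <- e + 1L
  }
  reps <- if (length(reps)) do.call(rbind, reps) else
    data.frame(start_time = numeric(0), peak_time = numeric(0),
               end_time = numeric(0), start_index = integer(0),
               peak_index = integer(0), end_index = integer(0),
               depth = numeric(0), plateau = logical(0))
  keep <- (reps$end_time - reps$start_time) >= params$min_duration &
    reps$depth >= params$min_depth
  reps <- reps[keep, , drop = FALSE]
  rownames(reps) <- NULL
  marks <- structure(
    list(reps = reps, rate = rate, baseline_value = baseline_value,
         expected_reps = expected_reps,
         count_mismatch = !is.null(expected_reps) && nrow(reps) != expected_reps),
    class = "repetition_marks")
  marks
}

interp_crossing <- function(t0, t1, y0, y1, level) {
  if (y1 == y0) return(t1)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Validate detected repetition marks against the expected count
#'
#' @param marks a `repetition_marks` object.
#' @param expected_reps expected repetition count.
#' @param mode `"strict"` errors on a mismatch; `"permissive"` flags it and
#'   lets the analysis proceed on all detected repetitions.
#' @return the marks, with `count_mismatch` updated.
#' @export
validate_marks <- function(marks, expected_reps,
                           mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(marks, "repetition_marks"))
  found <- nrow(marks$reps)
  marks$expected_reps <- expected_reps
  marks$count_mismatch <- found != expected_reps
  if (marks$count_mismatch && mode == "strict")
    stop(sprintf("repetition count mismatch: detected %d, expected %d",
                 found, expected_reps))
  marks
}

#' Segment a processed recording
#'
#' Convenience wrapper: quiet-standing baseline, repetition detection on the
#' vertical-displacement channel, count validation.
#'
#' @param kinematics a `pelvic_kinematics` series.
#' @param expected_reps expected repetition count (or `NULL`).
#' @param params a [segmentation_params()].
#' @param quiet_duration pre-task quiet span, s.
#' @param mode see [validate_marks()].
#' @inheritParams find_baseline
#' @return a `repetition_marks` object with `$baseline` attached.
#' @export
segment_recording <- function(kinematics, expected_reps = NULL,
                              params = segmentation_params(),
                              quiet_duration = 5, stability_window = 0.5,
                              var_ceiling = 4,
                              mode = c("permissive", "strict")) {
  mode <- match.arg(mode)
  baseline <- find_baseline(kinematics, quiet_duration, stability_window,
                            var_ceiling)
  marks <- detect_repetitions(kinematics$data$vertical, kinematics$rate,
                              baseline_value = baseline$values[["vertical"]],
                              params = params, expected_reps = expected_reps,
                              search_start = quiet_duration)
  marks$baseline <- baseline
  if (!is.null(expected_reps)) marks <- validate_marks(marks, expected_reps, mode)
  marks
}

#' @export
print.repetition_marks <- function(x, ...) {
  cat(sprintf("<repetition_marks> %d repetition(s) @ %g Hz\n", nrow(x$reps), x$rate))
  if (nrow(x$reps)) print(round(x$reps[c("start_time", "peak_time", "end_time", "depth")], 3))
  if (isTRUE(x$count_mismatch))
    cat(sprintf("  ! count mismatch: expected %d\n", x$expected_reps))
  invisible(x)
}

#' Serialize repetition marks to JSON (for manual correction and re-runs)
#' @param marks a `repetition_marks` object.
#' @param path output file path.
#' @export
write_marks_json <- function(marks, path) {
  jsonlite::write_json(
    list(rate = marks$rate, baseline_value = marks$baseline_value,
         baseline = marks$baseline, reps = marks$reps),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read repetition marks from JSON
#' @param path file written by [write_marks_json()] (possibly hand-edited).
#' @export
read_marks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(reps = as.data.frame(x$reps), rate = x$rate,
                 baseline_value = x$baseline_value,
                 baseline = list(index = x$baseline$index,
                                 time = x$baseline$time,
                                 values = unlist(x$baseline$values)),
                 expected_reps = NULL, count_mismatch = FALSE),
            class = "repetition_marks")
}
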