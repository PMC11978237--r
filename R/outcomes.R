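#' Baseline-referenced pelvic orientation at peak squat
#'
#' For each repetition, the mean of each angle channel over a window centered
#' on the identified peak (all samples within +-window/2, inclusive, so the
#' window is symmetric and its mean equals the instantaneous value at the
#' peak for signals linear through it), minus the baseline value of that
#' channel.
#'
#' @param kinematics a `pelvic_kinematics` series.
#' @param marks a `repetition_marks` object with `$baseline`.
#' @param window window width, s (default 0.2).
#' @param mode `"strict"` errors when the window exceeds the recording;
#'   `"permissive"` truncates it and flags the repetition.
#' @return data.frame (one row per repetition) with columns transverse,
#'   frontal, sagittal (deg) and `truncated_window`.
#' @export
orientation_at_peak <- function(kinematics, marks, window = 0.2,
                                mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kinematics, "pelvic_kinematics"),
            inherits(marks, "repetition_marks"))
  if (is.null(marks$baseline)) stop("marks carry no baseline; run segment_recording()")
  t <- series_time(kinematics)
  half <- window / 2
  planes <- c("transverse", "frontal", "sagittal")
  out <- lapply(seq_len(nrow(marks$reps)), function(k) {
    pk <- marks$reps$peak_time[k]
    idx <- which(t >= pk - half - 1e-9 & t <= pk + half + 1e-9)
    truncated <- pk - half < t[1] - 1e-9 || pk + half > t[length(t)] + 1e-9
    if (truncated && mode == "strict")
      stop(sprintf("peak window of repetition %d exceeds the recording bounds", k))
    if (length(idx) < 1L) stop("peak window contains no samples")
    deltas <- vapply(planes, function(ch) {
      mean(kinematics$data[[ch]][idx]) - marks$baseline$values[[ch]]
    }, numeric(1))
    data.frame(t(deltas), truncated_window = truncated)
  })
  do.call(rbind, out)
}

#' Repetition durations
#'
#' End minus start time, both refined by linear interpolation of the exit-
#' threshold crossings during detection.
#'
#' @param marks a `repetition_marks` object.
#' @return numeric vector of durations, s.
#' @export
rep_duration <- function(marks) {
  stopifnot(inherits(marks, "repetition_marks"))
  marks$reps$end_time - marks$reps$start_time
}

#' Mediolateral acceleration variability per repetition
#'
#' Sample standard deviation of the (filtered) mediolateral acceleration
#' between the start and end of each repetition.
#'
#' @param kinematics a `pelvic_kinematics` series with an `ml_accel` channel.
#' @param marks a `repetition_marks` object.
#' @return numeric vector, m/s^2.
#' @export
ml_variability <- function(kinematics, marks) {
  stopifnot(inherits(kinematics, "pelvic_kinematics"),
            inherits(marks, "repetition_marks"))
  t <- series_time(kinematics)
  vapply(seq_len(nrow(marks$reps)), function(k) {
    idx <- which(t >= marks$reps$start_time[k] & t <= marks$reps$end_time[k])
    stats::sd(kinematics$data$ml_accel[idx])
  }, numeric(1))
}

#' Per-repetition outcomes of one recording
#'
#' @param kinematics a `pelvic_kinematics` series.
#' @param marks a `repetition_marks` object with baseline.
#' @param window peak-window width, s.
#' @param mode window bounds handling, see [orientation_at_peak()].
#' @return data.frame: one row per repetition with duration (s),
#'   ml_accel_sd (m/s^2), transverse, frontal, sagittal (deg).
#' @export
repetition_outcomes <- function(kinematics, marks, window = 0.2,
                                mode = c("strict", "permissive")) {
  ang <- orientation_at_peak(kinematics, marks, window, mode)
  data.frame(duration = rep_duration(marks),
             ml_accel_sd = ml_variability(kinematics, marks),
             ang[c("transverse", "frontal", "sagittal")])
}

#' Per-task summary: median across repetitions
#'
#' Componentwise median over the repetitions of one task (even counts give
#' the mean of the middle two), the per-task value entering the agreement
#' and between-task analyses.
#'
#' @param rep_outcomes data.frame from [repetition_outcomes()].
#' @param participant participant id.
#' @param task task label (`"SLS"`, `"SD15"`, `"SD20"`).
#' @param source `"mocap"` or `"phone"`.
#' @param drift_fail logical heading-drift QC flag to carry forward.
#' @param count_mismatch logical repetition-count flag to carry forward.
#' @return one-row data.frame with the median outcomes, `n_reps` and flags.
#' @export
summarize_task <- function(rep_outcomes, participant, task, source,
                           drift_fail = FALSE, count_mismatch = FALSE) {
  if (nrow(rep_outcomes) < 1L) stop("no repetition outcomes to summarise")
  cols <- c("duration", "ml_accel_sd", "transverse", "frontal", "sagittal")
  med <- vapply(cols, function(ch) stats::median(rep_outcomes[[ch]]), numeric(1))
  data.frame(participant = participant, task = task, source = source,
             t(med), n_reps = nrow(rep_outcomes),
             drift_fail = drift_fail, count_mismatch = count_mismatch)
}
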