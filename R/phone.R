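#' Map device orientation channels to pelvic angles
#'
#' Converts the smartphone's roll/pitch/azimuth channels to the shared
#' pelvic-angle convention for the sacral landscape mounting (screen outward,
#' camera to the left): roll -> sagittal, pitch -> frontal, azimuth ->
#' transverse, all signs identity under the mounting's axis alignment (the
#' simulator and this processor share the table, so correctness is asserted
#' by round-trip). Azimuth is unwrapped across the +-180 degree seam and
#' re-referenced to its own quiet-standing median so the arbitrary
#' magnetometer heading zero never enters the outcomes.
#'
#' @param recording a `phone_recording`.
#' @param ref_window length-2 time window (s) of quiet standing used to
#'   re-reference azimuth.
#' @param max_step_deg largest admissible azimuth change between adjacent
#'   samples after unwrapping (default 90 deg, i.e. 9000 deg/s at 100 Hz -
#'   far beyond any pelvic motion, far below the ambiguous zone where a
#'   wrap correction could masquerade as motion); larger residual steps
#'   raise a corrupt-orientation error.
#' @return data.frame with columns transverse, frontal, sagittal (deg).
#' @export
to_pelvic_angles <- function(recording, ref_window = c(0, 2),
                             max_step_deg = 90) {
  stopifnot(inherits(recording, "phone_recording"))
  azim <- unwrap_deg(recording$data$azimuth)
  if (any(abs(diff(azim)) > max_step_deg))
    stop(sprintf("corrupt orientation: azimuth steps exceed %g degrees between adjacent samples after unwrapping",
                 max_step_deg))
  t <- series_time(recording)
  ref_idx <- which(t >= ref_window[1] & t <= ref_window[2])
  if (length(ref_idx) < 1L) stop("azimuth reference window contains no samples")
  data.frame(
    transverse = azim - stats::median(azim[ref_idx]),
    frontal = recording$data$pitch,
    sagittal = recording$data$roll
  )
}

# Unwrap a degree signal across the +-180 seam (adds multiples of 360 so that
# consecutive differences stay within (-180, 180]).
unwrap_deg <- function(x) {
  d <- diff(x)
  corr <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  x + c(0, corr)
}

#' Lab-vertical acceleration from the device channels
#'
#' Projects the measured specific force onto the laboratory vertical axis
#' using the device's own gravity-referenced tilt channels (roll and pitch;
#' heading does not enter the vertical projection). Without this projection,
#' gravity modulated by pelvic tilt leaks into the device vertical channel at
#' the squat frequency (about g times (1 - cos tilt)) and can largely cancel
#' the true vertical acceleration for strongly tilted participants. The
#' constant gravity term survives the projection and is removed by the
#' drift high-pass of the double integration, so the result is valid for
#' both gravity-inclusive and gravity-free ("linear acceleration") channel
#' semantics.
#'
#' @param recording a `phone_recording`.
#' @return numeric vector, m/s^2 (contains a constant near g when the
#'   channels include gravity; see Details).
#' @export
vertical_acceleration_lab <- function(recording) {
  stopifnot(inherits(recording, "phone_recording"))
  b <- deg2rad(recording$data$pitch)   # frontal tilt
  cc <- deg2rad(recording$data$roll)   # sagittal tilt
  cos(b) * cos(cc) * recording$data$ax -
    sin(b) * recording$data$ay -
    cos(b) * sin(cc) * recording$data$az
}

#' Vertical displacement estimate by drift-corrected double integration
#'
#' Pipeline: high-pass the acceleration, integrate (trapezoid, zero initial
#' conditions), high-pass the velocity, integrate, high-pass the
#' displacement - the drift filter applied at each step of the double
#' integration. The resulting waveform is shape-distorted at very low
#' frequencies by design; it is used only to identify repetition events, not
#' as a displacement outcome.
#'
#' @param acceleration vertical acceleration channel, m/s^2 (gravity may be
#'   included; the high-pass removes it).
#' @param rate sampling rate, Hz.
#' @param drift_filter [filter_spec()] for the drift high-pass
#'   (default 2nd-order Butterworth, 0.1 Hz).
#' @param passes 3 (filter acceleration, velocity and displacement) or 2
#'   (filter before each integration only).
#' @return displacement vector, m.
#' @export
estimate_vertical_displacement <- function(acceleration, rate,
                                           drift_filter = filter_spec("high", 2, 0.1),
                                           passes = 3) {
  if (!passes %in% c(2, 3)) stop("`passes` must be 2 or 3")
  if (length(acceleration) / rate < 4)
    stop("signal too short for drift-filtered double integration (need >= 4 s)")
  dt <- 1 / rate
  a <- apply_filter(acceleration, rate, drift_filter)
  v <- apply_filter(cumtrapz_dt(a, dt), rate, drift_filter)
  d <- cumtrapz_dt(v, dt)
  if (passes == 3) d <- apply_filter(d, rate, drift_filter)
  d
}

#' Mediolateral acceleration channel for variability analysis
#'
#' Zero-phase 4th-order 1 Hz high-pass of the device mediolateral
#' acceleration channel; removes gravity leakage and posture offsets while
#' preserving the sway band.
#'
#' @param recording a `phone_recording`.
#' @param accel_filter [filter_spec()] (default high-pass, order 4, 1 Hz).
#' @return filtered acceleration vector, m/s^2.
#' @export
prepare_ml_acceleration <- function(recording,
                                    accel_filter = filter_spec("high", 4, 1)) {
  stopifnot(inherits(recording, "phone_recording"))
  apply_filter(recording$data$ay, recording$rate, accel_filter)
}

#' Low-pass the orientation channels
#'
#' @param angles data.frame of angle channels (deg).
#' @param rate sampling rate, Hz.
#' @param orientation_filter [filter_spec()] (default low-pass, order 4, 10 Hz).
#' @return data.frame of filtered channels.
#' @export
filter_orientation <- function(angles, rate,
                               orientation_filter = filter_spec("low", 4, 10)) {
  for (ch in names(angles)) {
    angles[[ch]] <- apply_filter(angles[[ch]], rate, orientation_filter)
  }
  angles
}

#' Heading drift quality control
#'
#' Compares the transverse-channel medians in the pre-task and post-task
#' quiet-standing windows. A recording whose heading moved by more than the
#' threshold between the two windows is flagged for exclusion from
#' transverse-plane analyses (mirroring visual drift screening).
#'
#' @param kinematics a `pelvic_kinematics` series, or a data.frame of angle
#'   channels together with `rate`.
#' @param pre_window,post_window length-2 time windows (s); `post_window =
#'   NULL` uses the final 2 s of the recording.
#' @param threshold_deg drift threshold in degrees (default 5).
#' @param rate sampling rate, required when `kinematics` is a data.frame.
#' @return list with `status` ("pass", "fail" or "not-assessable") and
#'   `drift` (deg, post minus pre median).
#' @export
qc_heading_drift <- function(kinematics, pre_window = c(0, 4),
                             post_window = NULL, threshold_deg = 5,
                             rate = NULL) {
  if (inherits(kinematics, "uniform_series")) {
    x <- kinematics$data$transverse
    rate <- kinematics$rate
  } else {
    if (is.null(rate)) stop("`rate` required for plain data input")
    x <- kinematics$transverse
  }
  n <- length(x)
  t <- (seq_len(n) - 1L) / rate
  if (is.null(post_window)) post_window <- c(max(0, t[n] - 2), t[n])
  pre_idx <- which(t >= pre_window[1] & t <= pre_window[2])
  post_idx <- which(t >= post_window[1] & t <= post_window[2])
  if (length(pre_idx) < 2L || length(post_idx) < 2L ||
      post_window[1] <= pre_window[2]) {
    return(list(status = "not-assessable", drift = NA_real_))
  }
  drift <- stats::median(x[post_idx]) - stats::median(x[pre_idx])
  list(status = if (abs(drift) > threshold_deg) "fail" else "pass",
       drift = drift)
}

#' Process the smartphone branch to pelvic kinematics
#'
#' Runs the device pipeline: channel mapping and azimuth unwrap/re-reference,
#' 10 Hz low-pass on the angles, drift-corrected double integration of the
#' lab-vertical acceleration (tilt-projected specific force, see
#' [vertical_acceleration_lab()]) for the event-identification displacement,
#' and the
#' 1 Hz high-pass on the mediolateral acceleration. The mediolateral
#' displacement channel is the analogous double integral of the mediolateral
#' acceleration (event use only).
#'
#' @param recording a `phone_recording`.
#' @param orientation_filter,accel_filter,drift_filter [filter_spec()]s.
#' @param integration_passes drift-filter applications in the double
#'   integration (2 or 3; see [estimate_vertical_displacement()]).
#' @param ref_window quiet-standing window (s) for the azimuth reference.
#' @return a `pelvic_kinematics` series, source tag `"phone"`.
#' @export
process_phone <- function(recording,
                          orientation_filter = filter_spec("low", 4, 10),
                          accel_filter = filter_spec("high", 4, 1),
                          drift_filter = filter_spec("high", 2, 0.1),
                          integration_passes = 3,
                          ref_window = c(0, 2)) {
  stopifnot(inherits(recording, "phone_recording"))
  rate <- recording$rate
  ang <- filter_orientation(to_pelvic_angles(recording, ref_window), rate,
                            orientation_filter)
  vert <- estimate_vertical_displacement(vertical_acceleration_lab(recording),
                                         rate, drift_filter, integration_passes)
  ml_disp <- estimate_vertical_displacement(recording$data$ay, rate,
                                            drift_filter, integration_passes)
  ml_acc <- prepare_ml_acceleration(recording, accel_filter)
  kin <- uniform_series(cbind(ang, vertical = vert, mediolateral = ml_disp,
                              ml_accel = ml_acc),
                        rate = rate, start = recording$start)
  kin$source <- "phone"
  class(kin) <- c("pelvic_kinematics", "uniform_series")
  kin
}
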