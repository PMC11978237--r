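#' Pelvic orientation from the four-marker cluster
#'
#' Builds an orthonormal pelvis frame at every sample - the mediolateral
#' axis from the ASIS marker pair, the anteroposterior axis toward the
#' mid-ASIS point from the mid-PSIS point (orthogonalised against the
#' mediolateral axis), vertical completing the right-handed triad - then
#' decomposes the rotation from the reference frame with the shared Euler
#' convention and sign table (see [conventions]).
#'
#' @param markers a `marker_set` (see [render_mocap()] / [read_marker_csv()]).
#' @param reference 3x3 reference frame matrix (columns = pelvis axes in lab
#'   coordinates), or `NULL` to use the first sample, or a numeric length-2
#'   time window (s) whose mean marker positions define the frame. Using the
#'   quiet-standing window means a participant standing slightly rotated
#'   reads zero, consistent with baseline subtraction in the outcomes.
#' @return data.frame with columns transverse, frontal, sagittal (deg).
#' @export
orientation_from_markers <- function(markers, reference = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  f <- marker_frames(markers)
  if (is.null(reference)) {
    ref <- matrix(c(f$x1[1], f$x2[1], f$x3[1],
                    f$y1[1], f$y2[1], f$y3[1],
                    f$z1[1], f$z2[1], f$z3[1]), 3L, 3L)
  } else if (is.matrix(reference)) {
    ref <- reference
  } else if (is.numeric(reference) && length(reference) == 2L) {
    ref <- reference_frame(markers, reference)
  } else {
    stop("`reference` must be NULL, a 3x3 matrix or a length-2 time window")
  }
  # relative rotation R = F_t %*% t(F_ref); F columns are the body axes
  r <- list()
  refc <- list(x = ref[, 1], y = ref[, 2], z = ref[, 3])
  ft <- list(x = cbind(f$x1, f$x2, f$x3),
             y = cbind(f$y1, f$y2, f$y3),
             z = cbind(f$z1, f$z2, f$z3))
  for (ii in 1:3) for (jj in 1:3) {
    r[[paste0("r", ii, jj)]] <-
      ft$x[, ii] * refc$x[jj] + ft$y[, ii] * refc$y[jj] + ft$z[, ii] * refc$z[jj]
  }
  angles_from_components(r)
}

# Per-sample orthonormal pelvis frame from the marker cluster. Returns the
# three axis vectors as 9 per-sample component vectors (x=vertical axis,
# y=mediolateral, z=anteroposterior; suffix 1/2/3 = lab component).
marker_frames <- function(markers) {
  d <- markers$data
  get <- function(lab, ax) d[[paste(lab, ax, sep = "_")]]
  y1 <- get("LASIS", "x") - get("RASIS", "x")
  y2 <- get("LASIS", "y") - get("RASIS", "y")
  y3 <- get("LASIS", "z") - get("RASIS", "z")
  ny <- sqrt(y1^2 + y2^2 + y3^2)
  midax <- function(ax) (get("LASIS", ax) + get("RASIS", ax)) / 2
  midpx <- function(ax) (get("LPSIS", ax) + get("RPSIS", ax)) / 2
  z1 <- midax("x") - midpx("x")
  z2 <- midax("y") - midpx("y")
  z3 <- midax("z") - midpx("z")
  if (any(ny < 1e-9)) stop("degenerate marker geometry: ASIS markers coincide")
  y1 <- y1 / ny; y2 <- y2 / ny; y3 <- y3 / ny
  dot <- z1 * y1 + z2 * y2 + z3 * y3
  z1 <- z1 - dot * y1; z2 <- z2 - dot * y2; z3 <- z3 - dot * y3
  nz <- sqrt(z1^2 + z2^2 + z3^2)
  if (any(nz < 1e-9))
    stop("degenerate marker geometry: markers are collinear (ASIS axis parallel to PSIS->ASIS axis)")
  z1 <- z1 / nz; z2 <- z2 / nz; z3 <- z3 / nz
  # vertical completes the right-handed triad: x = y cross z
  x1 <- y2 * z3 - y3 * z2
  x2 <- y3 * z1 - y1 * z3
  x3 <- y1 * z2 - y2 * z1
  list(x1 = x1, x2 = x2, x3 = x3, y1 = y1, y2 = y2, y3 = y3,
       z1 = z1, z2 = z2, z3 = z3)
}

# Reference frame from mean marker positions over a time window.
reference_frame <- function(markers, window) {
  t <- series_time(markers)
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 1L) stop("reference window contains no samples")
  avg <- markers
  avg$data <- as.data.frame(lapply(markers$data, function(col) {
    rep(mean(col[idx]), 2L)
  }))
  class(avg) <- class(markers)
  f <- marker_frames(avg)
  matrix(c(f$x1[1], f$x2[1], f$x3[1],
           f$y1[1], f$y2[1], f$y3[1],
           f$z1[1], f$z2[1], f$z3[1]), 3L, 3L)
}

#' Centroid displacement of the marker cluster
#'
#' Per-sample mean of the four marker positions projected on the vertical and
#' mediolateral lab axes - the displacement signals used for repetition
#' segmentation and (after double differentiation) mediolateral acceleration.
#'
#' @param markers a `marker_set`.
#' @return data.frame with columns vertical, mediolateral (m).
#' @export
centroid_displacement <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  d <- markers$data
  data.frame(
    vertical = (d$LASIS_x + d$RASIS_x + d$LPSIS_x + d$RPSIS_x) / 4,
    mediolateral = (d$LASIS_y + d$RASIS_y + d$LPSIS_y + d$RPSIS_y) / 4
  )
}

#' Double differentiation of a displacement channel
#'
#' Two applications of central differences (one-sided at the edges),
#' length-preserving; exact for quadratic displacement.
#'
#' @param x numeric displacement vector, m.
#' @param rate sampling rate, Hz.
#' @return acceleration vector, m/s^2.
#' @export
double_differentiate <- function(x, rate) {
  if (length(x) < 5L) stop("need at least 5 samples to double-differentiate")
  grad_dt(grad_dt(x, 1 / rate), 1 / rate)
}

#' Process the motion-capture branch to pelvic kinematics
#'
#' Runs the full marker pipeline: orientation from the cluster (reference =
#' quiet-standing mean frame), zero-phase 10 Hz low-pass on the angles;
#' centroid displacement relative to the quiet-standing mean, low-passed
#' before differentiation to keep marker noise out of the acceleration;
#' double differentiation of the mediolateral displacement followed by the
#' 1 Hz high-pass.
#'
#' @param markers a `marker_set`.
#' @param orientation_filter [filter_spec()] for the angle channels.
#' @param accel_filter [filter_spec()] for the acceleration channel.
#' @param displacement_lowpass cutoff (Hz) of the 4th-order low-pass applied
#'   to the centroid displacement before differentiation; marker noise
#'   double-differentiated at 250 Hz would otherwise swamp the sway signal.
#' @param ref_window length-2 time window (s) of quiet standing used for the
#'   reference frame and displacement zero.
#' @return a `pelvic_kinematics` series (channels transverse, frontal,
#'   sagittal (deg), vertical, mediolateral (m), ml_accel (m/s^2)), source
#'   tag `"mocap"`.
#' @export
process_mocap <- function(markers,
                          orientation_filter = filter_spec("low", 4, 10),
                          accel_filter = filter_spec("high", 4, 1),
                          displacement_lowpass = 6,
                          ref_window = c(0, 1)) {
  stopifnot(inherits(markers, "marker_set"))
  rate <- markers$rate
  ref <- reference_frame(markers, ref_window)
  ang <- orientation_from_markers(markers, reference = ref)
  for (ch in names(ang)) ang[[ch]] <- apply_filter(ang[[ch]], rate, orientation_filter)
  disp <- centroid_displacement(markers)
  t <- series_time(markers)
  base_idx <- which(t >= ref_window[1] & t <= ref_window[2])
  dl <- filter_spec("low", 4, displacement_lowpass)
  for (ch in names(disp)) {
    disp[[ch]] <- apply_filter(disp[[ch]] - mean(disp[[ch]][base_idx]), rate, dl)
  }
  ml_acc <- apply_filter(double_differentiate(disp$mediolateral, rate),
                         rate, accel_filter)
  kin <- uniform_series(cbind(ang, disp, ml_accel = ml_acc), rate = rate,
                        start = markers$start)
  kin$source <- "mocap"
  class(kin) <- c("pelvic_kinematics", "uniform_series")
  kin
}
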