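#' Default pelvis marker geometry
#'
#' Local coordinates of the four pelvis markers (bilateral anterior and
#' posterior superior iliac spines) in the pelvis frame, meters, axes
#' (vertical, mediolateral, anteroposterior). The ASIS pair sits +-120 mm
#' mediolaterally and 90 mm anterior of the cluster origin, the PSIS pair
#' +-60 mm mediolaterally and 90 mm posterior, all at the same height --
#' a typical adult pelvis on the scale of the marker protocol used with
#' sacrum-mounted sensing.
#'
#' @param asis_halfwidth,psis_halfwidth half the mediolateral marker spacing, m.
#' @param depth anteroposterior distance from origin to each pair, m.
#' @return 4x3 matrix with rownames LASIS, RASIS, LPSIS, RPSIS.
#' @export
marker_geometry <- function(asis_halfwidth = 0.120, psis_halfwidth = 0.060,
                            depth = 0.090) {
  g <- rbind(
    LASIS = c(0,  asis_halfwidth,  depth),
    RASIS = c(0, -asis_halfwidth,  depth),
    LPSIS = c(0,  psis_halfwidth, -depth),
    RPSIS = c(0, -psis_halfwidth, -depth)
  )
  colnames(g) <- c("vertical", "mediolateral", "anteroposterior")
  g
}

marker_labels <- c("LASIS", "RASIS", "LPSIS", "RPSIS")

#' Simulation configuration
#'
#' Bundles every knob of the paired-recording generator. The defaults encode
#' the study protocol (5 repetitions at a 4-second tempo, 2-second rests,
#' 5 seconds of quiet standing before the task) and realistic per-task
#' kinematics: per-plane peak-angle locations are the smartphone task medians
#' reported for this protocol, with their spread split into a participant
#' intercept shared across tasks and a smaller task-specific component so
#' that within-participant task contrasts have realistic power. Mediolateral
#' sway intensity is specified directly as the target standard deviation of
#' the true mediolateral acceleration during a repetition.
#'
#' @param n_participants number of simulated participants.
#' @param tasks subset of `c("SLS","SD15","SD20")`.
#' @param reps_per_task repetitions per task (default 5).
#' @param rep_duration nominal down-and-up duration, s (default 4).
#' @param rep_duration_sd between-participant SD of the repetition duration, s.
#'   Draws are truncated to [2.5, 6] s. Set 0 for the idealised fixed-tempo
#'   protocol.
#' @param rest_duration rest between repetitions, s (default 2).
#' @param quiet_duration quiet standing before the task, s (default 5).
#' @param post_quiet quiet standing after the task, s (used by the heading
#'   drift QC).
#' @param plateau_fraction fraction of the repetition spent paused at maximal
#'   depth (default 0 = continuous down-and-up).
#' @param squat_depth named per-task pelvis lowering at peak squat, m
#'   (positive = lowering). Not reported by the study; defaults are an
#'   assumption on the 0.1-0.2 m scale implied by 60-80 degrees of knee
#'   flexion, and are irrelevant to angle-recovery behaviour.
#' @param squat_depth_sd between-participant SD of the depth, m.
#' @param angle_location 3x3 matrix (tasks x planes), deg: per-task location
#'   of the true peak angles.
#' @param angle_participant_sd per-plane SD of the participant intercept, deg.
#' @param angle_task_sd per-plane SD of the task-specific deviation, deg.
#' @param ml_accel_location named per-task target SD of true mediolateral
#'   acceleration during a repetition, m/s^2.
#' @param ml_accel_participant_sd,ml_accel_task_sd spread of the sway
#'   intensity across participants / tasks, m/s^2.
#' @param sway_freq_range frequency band of the simulated sway, Hz.
#' @param marker_noise_sd isotropic marker position noise, m.
#' @param phone_accel_noise_sd accelerometer noise, m/s^2.
#' @param phone_orient_noise_sd orientation channel noise, deg.
#' @param mounting_offset named constant device mounting offset, deg
#'   (transverse, frontal, sagittal).
#' @param heading_drift_rate slow heading (transverse) drift of the device
#'   orientation, deg/s.
#' @param gravity gravitational acceleration, m/s^2.
#' @param include_gravity if `TRUE` the simulated acceleration channels are
#'   accelerometer-like (specific force, gravity included); if `FALSE` they
#'   are "linear acceleration"-like. Outcomes are insensitive to the choice
#'   because acceleration is high-pass filtered and displacement is used only
#'   for event identification.
#' @param master_rate internal rendering rate, Hz; must be a common multiple
#'   of the two sensor rates.
#' @param mocap_rate,phone_rate output rates of the two branches, Hz.
#' @param sex_effect named list of additive effects for male participants
#'   (applied to `duration` in seconds); default no sex differences.
#' @param seed RNG seed; fixes the whole cohort byte-for-byte.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(
    n_participants = 10,
    tasks = c("SLS", "SD15", "SD20"),
    reps_per_task = 5,
    rep_duration = 4.0,
    rep_duration_sd = 0.35,
    rest_duration = 2.0,
    quiet_duration = 5.0,
    post_quiet = 3.0,
    plateau_fraction = 0,
    squat_depth = c(SLS = 0.14, SD15 = 0.18, SD20 = 0.22),
    squat_depth_sd = 0.03,
    angle_location = rbind(
      SLS  = c(transverse = -6.4, frontal = -0.9, sagittal =  0.9),
      SD15 = c(transverse = -1.2, frontal =  3.4, sagittal = -3.2),
      SD20 = c(transverse = -0.2, frontal =  4.5, sagittal = -1.3)),
    angle_participant_sd = c(transverse = 4.5, frontal = 3.0, sagittal = 6.8),
    angle_task_sd = c(transverse = 2.5, frontal = 1.1, sagittal = 2.2),
    ml_accel_location = c(SLS = 0.15, SD15 = 0.17, SD20 = 0.19),
    ml_accel_participant_sd = 0.045,
    ml_accel_task_sd = 0.02,
    sway_freq_range = c(1.5, 2.5),
    marker_noise_sd = 0.0003,
    phone_accel_noise_sd = 0.02,
    phone_orient_noise_sd = 0.2,
    mounting_offset = c(transverse = 0, frontal = 0, sagittal = 0),
    heading_drift_rate = 0,
    gravity = 9.81,
    include_gravity = TRUE,
    master_rate = 500,
    mocap_rate = 250,
    phone_rate = 100,
    sex_effect = list(duration = 0),
    seed = NULL) {
  tasks <- match.arg(tasks, c("SLS", "SD15", "SD20"), several.ok = TRUE)
  if (rep_duration <= 0) stop("`rep_duration` must be positive")
  if (rest_duration <= 0 || quiet_duration <= 0 || post_quiet < 0)
    stop("durations must be positive")
  if (any(squat_depth[tasks] < 0))
    stop("`squat_depth` must be non-negative: squatting lowers the pelvis")
  sds <- c(marker_noise_sd, phone_accel_noise_sd, phone_orient_noise_sd,
           squat_depth_sd, rep_duration_sd, angle_participant_sd,
           angle_task_sd, ml_accel_participant_sd, ml_accel_task_sd)
  if (any(sds < 0)) stop("noise/spread SDs must be >= 0")
  if (plateau_fraction < 0 || plateau_fraction >= 1)
    stop("`plateau_fraction` must be in [0, 1)")
  if (master_rate %% mocap_rate != 0 || master_rate %% phone_rate != 0)
    stop("`master_rate` must be an integer multiple of both sensor rates")
  if (master_rate < 500)
    stop("`master_rate` must be at least 500 Hz")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Normalised down-and-up motion profile on u in [0,1]: raised-cosine descent
# and ascent with an optional flat plateau at the bottom. 0 at both ends,
# 1 at the bottom; continuous first derivative.
motion_profile <- function(u, plateau_fraction = 0) {
  s <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  if (plateau_fraction <= 0) {
    s[inside] <- (1 - cos(2 * pi * u[inside])) / 2
  } else {
    half <- (1 - plateau_fraction) / 2
    ui <- u[inside]
    si <- numeric(length(ui))
    lo <- ui < half
    hi <- ui > 1 - half
    si[lo] <- (1 - cos(pi * ui[lo] / half)) / 2
    si[hi] <- (1 - cos(pi * (1 - ui[hi]) / half)) / 2
    si[!lo & !hi] <- 1
    s[inside] <- si
  }
  s
}

# Central-difference derivative, one-sided at the edges; length preserving.
grad_dt <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  c(x[2] - x[1],
    (x[3:n] - x[1:(n - 2L)]) / 2,
    x[n] - x[n - 1L]) / dt
}

#' Generate a ground-truth pelvis pose for one task
#'
#' Builds the latent pose every rendered recording derives from: three pelvic
#' angle channels, vertical displacement and mediolateral sway at the master
#' rate, plus the true start/peak/end times and true peak angles of every
#' repetition. Each repetition follows a raised-cosine descent/ascent; the
#' angle channels are the per-plane peak amplitude times the same normalised
#' profile, so the true peak angle of each repetition equals the amplitude.
#'
#' Amplitudes, depth, pace and sway intensity default to draws from the
#' configured distributions (using the current RNG state); pass them
#' explicitly for fully deterministic poses.
#'
#' @param config a [sim_config()].
#' @param task one of the configured task labels.
#' @param amplitudes named per-plane peak angles, deg (optional).
#' @param depth squat depth, m (optional, positive = lowering).
#' @param rep_duration repetition duration, s (optional).
#' @param ml_accel_target target SD of true mediolateral acceleration during
#'   a repetition, m/s^2 (optional).
#' @return an object of class `pose_trajectory` (a [uniform_series()] with
#'   channels transverse/frontal/sagittal (deg), vertical/mediolateral (m),
#'   plus `$events`, `$true_peaks` and `$params`).
#' @export
generate_pose <- function(config, task, amplitudes = NULL, depth = NULL,
                          rep_duration = NULL, ml_accel_target = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!task %in% config$tasks) stop(sprintf("task '%s' not in config$tasks", task))
  planes <- c("transverse", "frontal", "sagittal")
  if (is.null(amplitudes)) {
    tot_sd <- sqrt(config$angle_participant_sd^2 + config$angle_task_sd^2)
    amplitudes <- config$angle_location[task, planes] + stats::rnorm(3, 0, tot_sd[planes])
    names(amplitudes) <- planes
  }
  amplitudes <- amplitudes[planes]
  if (is.null(depth)) {
    depth <- max(0.05, stats::rnorm(1, config$squat_depth[[task]], config$squat_depth_sd))
  }
  if (depth < 0) stop("`depth` must be non-negative: squatting lowers the pelvis")
  if (is.null(rep_duration)) rep_duration <- config$rep_duration
  if (rep_duration <= 0) stop("`rep_duration` must be positive")
  if (is.null(ml_accel_target)) {
    ml_accel_target <- max(0.03, stats::rnorm(1, config$ml_accel_location[[task]],
                                              sqrt(config$ml_accel_participant_sd^2 +
                                                   config$ml_accel_task_sd^2)))
  }

  nrep <- config$reps_per_task
  starts <- config$quiet_duration +
    (seq_len(nrep) - 1L) * (rep_duration + config$rest_duration)
  ends <- starts + rep_duration
  peaks <- starts + rep_duration / 2
  total <- ends[nrep] + config$post_quiet
  rate <- config$master_rate
  t <- seq(0, total, by = 1 / rate)

  env <- numeric(length(t))
  for (k in seq_len(nrep)) {
    u <- (t - starts[k]) / rep_duration
    env <- env + motion_profile(u, config$plateau_fraction)
  }

  # band-limited sway under the repetition envelope, amplitude calibrated so
  # the true acceleration SD over the repetition spans hits the target
  ml <- numeric(length(t))
  if (ml_accel_target > 0) {
    freqs <- stats::runif(3, config$sway_freq_range[1], config$sway_freq_range[2])
    phases <- stats::runif(3, 0, 2 * pi)
    w <- c(1, 0.7, 0.5)
    m <- numeric(length(t))
    for (j in 1:3) m <- m + w[j] * sin(2 * pi * freqs[j] * t + phases[j])
    u_sig <- m * env
    acc_u <- grad_dt(grad_dt(u_sig, 1 / rate), 1 / rate)
    in_rep <- rep(FALSE, length(t))
    for (k in seq_len(nrep)) in_rep <- in_rep | (t >= starts[k] & t <= ends[k])
    sd_u <- stats::sd(acc_u[in_rep])
    if (sd_u > 0) ml <- (ml_accel_target / sd_u) * u_sig
  }

  data <- data.frame(
    transverse = amplitudes[["transverse"]] * env,
    frontal    = amplitudes[["frontal"]] * env,
    sagittal   = amplitudes[["sagittal"]] * env,
    vertical   = -depth * env,
    mediolateral = ml
  )
  pose <- uniform_series(data, rate = rate)
  pose$events <- data.frame(start = starts, peak = peaks, end = ends)
  pose$true_peaks <- amplitudes
  pose$params <- list(task = task, depth = depth, rep_duration = rep_duration,
                      ml_accel_target = ml_accel_target,
                      plateau_fraction = config$plateau_fraction,
                      quiet_duration = config$quiet_duration)
  class(pose) <- c("pose_trajectory", "uniform_series")
  pose
}

#' Render a marker-cluster recording from a ground-truth pose
#'
#' Places the four pelvis markers by rotating the local geometry with the
#' shared Euler convention, translating by the pose displacements,
#' decimating to the motion-capture rate and adding isotropic Gaussian
#' position noise. With zero noise the output is a perfect rigid body.
#'
#' @param pose a [generate_pose()] result.
#' @param geometry a [marker_geometry()] matrix.
#' @param noise_sd isotropic marker noise SD, m.
#' @param rate output rate, Hz (must divide the pose master rate).
#' @return a `marker_set` (a [uniform_series()] with 12 position channels
#'   `<LABEL>_{x,y,z}` where x/y/z = vertical/mediolateral/anteroposterior).
#' @export
render_mocap <- function(pose, geometry = marker_geometry(), noise_sd = 0,
                         rate = 250) {
  stopifnot(inherits(pose, "pose_trajectory"))
  if (pose$rate %% rate != 0) stop("output rate must divide the master rate")
  s <- decimate_series(pose, pose$rate / rate)
  r <- rotation_components(deg2rad(s$data$transverse),
                           deg2rad(s$data$frontal),
                           deg2rad(s$data$sagittal))
  n <- nrow(s$data)
  out <- vector("list", 12L)
  nm <- character(12L)
  i <- 1L
  for (lab in marker_labels) {
    p <- geometry[lab, ]
    px <- p[[1]]; py <- p[[2]]; pz <- p[[3]]
    out[[i]]     <- r$r11 * px + r$r12 * py + r$r13 * pz + s$data$vertical
    out[[i + 1]] <- r$r21 * px + r$r22 * py + r$r23 * pz + s$data$mediolateral
    out[[i + 2]] <- r$r31 * px + r$r32 * py + r$r33 * pz
    nm[i:(i + 2)] <- paste(lab, c("x", "y", "z"), sep = "_")
    i <- i + 3L
  }
  names(out) <- nm
  data <- as.data.frame(out)
  if (noise_sd > 0) {
    data[] <- lapply(data, function(col) col + stats::rnorm(n, 0, noise_sd))
  }
  mk <- uniform_series(data, rate = rate)
  mk$labels <- marker_labels
  class(mk) <- c("marker_set", "uniform_series")
  mk
}

wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Render a smartphone recording from a ground-truth pose
#'
#' Emits the six device channels at the phone rate: orientation as roll
#' (sagittal), pitch (frontal) and azimuth (transverse) equal to the pose
#' angles plus a constant mounting offset, slow heading drift (azimuth only)
#' and Gaussian noise, with azimuth wrapped to (-180, 180]; acceleration as
#' the specific force in the (offset) device frame - the second derivative of
#' the pose displacement rotated into the device frame, plus gravity along
#' the device vertical axis when `include_gravity` - plus noise.
#'
#' @param pose a [generate_pose()] result.
#' @param mounting_offset named deg vector (transverse, frontal, sagittal).
#' @param heading_drift_rate deg/s added to azimuth as rate * time.
#' @param accel_noise_sd,orient_noise_sd channel noise SDs (m/s^2, deg).
#' @param gravity gravitational acceleration, m/s^2.
#' @param include_gravity include gravity in the acceleration channels.
#' @param rate output rate, Hz (must divide the pose master rate).
#' @return a `phone_recording` (a [uniform_series()] with channels
#'   ax, ay, az, roll, pitch, azimuth).
#' @export
render_phone <- function(pose,
                         mounting_offset = c(transverse = 0, frontal = 0, sagittal = 0),
                         heading_drift_rate = 0,
                         accel_noise_sd = 0, orient_noise_sd = 0,
                         gravity = 9.81, include_gravity = TRUE,
                         rate = 100) {
  stopifnot(inherits(pose, "pose_trajectory"))
  if (pose$rate %% rate != 0) stop("output rate must divide the master rate")
  dt <- 1 / pose$rate
  acc_v_master <- grad_dt(grad_dt(pose$data$vertical, dt), dt)
  acc_m_master <- grad_dt(grad_dt(pose$data$mediolateral, dt), dt)
  fac <- pose$rate / rate
  keep <- seq(1L, n_samples(pose), by = fac)
  tt <- (keep - 1L) * dt
  n <- length(keep)

  ang <- pose$data[keep, c("transverse", "frontal", "sagittal")]
  av <- acc_v_master[keep]
  am <- acc_m_master[keep]

  # device orientation = pose composed with the constant mounting offset
  rp <- rotation_components(deg2rad(ang$transverse), deg2rad(ang$frontal),
                            deg2rad(ang$sagittal))
  ro <- pelvic_rotation(mounting_offset[["transverse"]],
                        mounting_offset[["frontal"]],
                        mounting_offset[["sagittal"]])
  # R_dev = R_pose %*% R_off, per sample
  rd <- list()
  for (ii in 1:3) for (jj in 1:3) {
    rd[[paste0("r", ii, jj)]] <-
      rp[[paste0("r", ii, "1")]] * ro[1, jj] +
      rp[[paste0("r", ii, "2")]] * ro[2, jj] +
      rp[[paste0("r", ii, "3")]] * ro[3, jj]
  }
  gx <- if (include_gravity) gravity else 0
  # specific force in device frame: t(R_dev) %*% (a_lab + g * e_vertical)
  fx_lab <- av + gx
  fy_lab <- am
  ax <- rd$r11 * fx_lab + rd$r21 * fy_lab
  ay <- rd$r12 * fx_lab + rd$r22 * fy_lab
  az <- rd$r13 * fx_lab + rd$r23 * fy_lab

  roll  <- ang$sagittal + mounting_offset[["sagittal"]]
  pitch <- ang$frontal + mounting_offset[["frontal"]]
  azim  <- ang$transverse + mounting_offset[["transverse"]] +
    heading_drift_rate * tt
  if (orient_noise_sd > 0) {
    roll  <- roll + stats::rnorm(n, 0, orient_noise_sd)
    pitch <- pitch + stats::rnorm(n, 0, orient_noise_sd)
    azim  <- azim + stats::rnorm(n, 0, orient_noise_sd)
  }
  if (accel_noise_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, accel_noise_sd)
    ay <- ay + stats::rnorm(n, 0, accel_noise_sd)
    az <- az + stats::rnorm(n, 0, accel_noise_sd)
  }
  data <- data.frame(ax = ax, ay = ay, az = az,
                     roll = roll, pitch = pitch, azimuth = wrap_deg(azim))
  ph <- uniform_series(data, rate = rate)
  class(ph) <- c("phone_recording", "uniform_series")
  ph
}

#' Simulate a full paired cohort
#'
#' Draws participant-level effects (per-plane intercepts shared across tasks,
#' pace, sway intensity), generates one pose per participant x task, and
#' renders both sensor streams from it. Deterministic under a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `pelvic_cohort`: a list with `$records` (each
#'   record holding participant id, sex, task, `$pose`, `$markers`,
#'   `$phone`) and `$config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  planes <- c("transverse", "frontal", "sagittal")
  records <- list()
  sexes <- rep(c("F", "M"), length.out = config$n_participants)
  for (p in seq_len(config$n_participants)) {
    id <- sprintf("P%02d", p)
    sex <- sexes[p]
    u_ang <- stats::rnorm(3, 0, config$angle_participant_sd[planes])
    names(u_ang) <- planes
    u_ml <- stats::rnorm(1, 0, config$ml_accel_participant_sd)
    dur_p <- min(6, max(2.5, stats::rnorm(1, config$rep_duration,
                                          config$rep_duration_sd)))
    if (sex == "M") dur_p <- min(6, dur_p + config$sex_effect$duration)
    for (task in config$tasks) {
      amps <- config$angle_location[task, planes] + u_ang +
        stats::rnorm(3, 0, config$angle_task_sd[planes])
      names(amps) <- planes
      depth <- max(0.05, stats::rnorm(1, config$squat_depth[[task]],
                                      config$squat_depth_sd))
      ml_t <- max(0.03, config$ml_accel_location[[task]] + u_ml +
                    stats::rnorm(1, 0, config$ml_accel_task_sd))
      pose <- generate_pose(config, task, amplitudes = amps, depth = depth,
                            rep_duration = dur_p, ml_accel_target = ml_t)
      markers <- render_mocap(pose, noise_sd = config$marker_noise_sd,
                              rate = config$mocap_rate)
      phone <- render_phone(pose,
                            mounting_offset = config$mounting_offset,
                            heading_drift_rate = config$heading_drift_rate,
                            accel_noise_sd = config$phone_accel_noise_sd,
                            orient_noise_sd = config$phone_orient_noise_sd,
                            gravity = config$gravity,
                            include_gravity = config$include_gravity,
                            rate = config$phone_rate)
      records[[paste(id, task, sep = "_")]] <-
        list(participant = id, sex = sex, task = task,
             pose = pose, markers = markers, phone = phone)
    }
  }
  structure(list(records = records, config = config), class = "pelvic_cohort")
}

#' @export
print.pelvic_cohort <- function(x, ...) {
  cat(sprintf("<pelvic_cohort> %d participants x %d task(s) = %d paired recordings\n",
              x$config$n_participants, length(x$config$tasks),
              length(x$records)))
  invisible(x)
}
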