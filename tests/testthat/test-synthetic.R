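test_that("the repetition schedule follows the protocol arithmetic", {
  cfg <- fast_config(seed = 1)
  pose <- generate_pose(cfg, "SLS", amplitudes = c(transverse = 0, frontal = 0, sagittal = 0),
                        depth = 0.1, rep_duration = 4, ml_accel_target = 0)
  # 5 s quiet + 5 reps x 4 s + 4 rests x 2 s
  expect_equal(pose$events$end[5], 33)
  expect_equal(pose$events$start, 5 + (0:4) * 6)
  expect_equal(pose$events$peak, pose$events$start + 2)
  # windows disjoint, separated by the configured rest
  gaps <- pose$events$start[-1] - pose$events$end[-5]
  expect_true(all(gaps >= cfg$rest_duration - 1e-12))
})

test_that("degenerate amplitude distributions give an identically null pose", {
  cfg <- fast_config(seed = 1)
  pose <- generate_pose(cfg, "SLS",
                        amplitudes = c(transverse = 0, frontal = 0, sagittal = 0),
                        depth = 0, ml_accel_target = 0)
  expect_true(all(abs(as.matrix(pose$data)) == 0))
  expect_equal(unname(pose$true_peaks), c(0, 0, 0))
})

test_that("raised-cosine peak vertical velocity matches the analytic value", {
  cfg <- fast_config(seed = 1)
  pose <- generate_pose(cfg, "SLS",
                        amplitudes = c(transverse = 0, frontal = 0, sagittal = 0),
                        depth = 0.10, rep_duration = 4, ml_accel_target = 0)
  v <- diff(pose$data$vertical) * pose$rate
  expect_equal(max(abs(v)), pi * 0.10 / 4, tolerance = 1e-4)
})

test_that("pose is at baseline outside repetitions and never above it inside", {
  cfg <- fast_config(seed = 3)
  pose <- generate_pose(cfg, "SD15",
                        amplitudes = c(transverse = -5, frontal = 4, sagittal = -3),
                        depth = 0.18, ml_accel_target = 0.17)
  t <- series_time(pose)
  in_rep <- rep(FALSE, length(t))
  for (k in 1:5) in_rep <- in_rep |
      (t > pose$events$start[k] & t < pose$events$end[k])
  expect_true(all(abs(as.matrix(pose$data[!in_rep, ])) < 1e-12))
  expect_true(all(pose$data$vertical <= 0))
})

test_that("zero-noise markers form an exactly rigid body", {
  cfg <- fast_config(seed = 4)
  pose <- generate_pose(cfg, "SLS",
                        amplitudes = c(transverse = -8, frontal = 6, sagittal = 12),
                        depth = 0.15, ml_accel_target = 0.2)
  mk <- render_mocap(pose, noise_sd = 0)
  d <- mk$data
  labs <- c("LASIS", "RASIS", "LPSIS", "RPSIS")
  pairs <- utils::combn(labs, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dist <- sqrt((d[[paste0(a, "_x")]] - d[[paste0(b, "_x")]])^2 +
                 (d[[paste0(a, "_y")]] - d[[paste0(b, "_y")]])^2 +
                 (d[[paste0(a, "_z")]] - d[[paste0(b, "_z")]])^2)
    expect_lt(max(dist) - min(dist), 1e-9)
  }
})

test_that("marker-implied orientation equals phone orientation minus offset and drift", {
  cfg <- fast_config(seed = 6)
  pose <- generate_pose(cfg, "SD20",
                        amplitudes = c(transverse = -4, frontal = 5, sagittal = -7),
                        depth = 0.2, ml_accel_target = 0.19)
  mk <- render_mocap(pose, noise_sd = 0)
  off <- c(transverse = 3, frontal = -2, sagittal = 5)
  ph <- render_phone(pose, mounting_offset = off, heading_drift_rate = 0.05)
  ang_mk <- orientation_from_markers(mk, reference = diag(3))
  # compare on the common 50 Hz subgrid
  i_mk <- seq(1, nrow(ang_mk), by = 5)
  i_ph <- seq(1, n_samples(ph), by = 2)
  t_ph <- series_time(ph)[i_ph]
  expect_equal(ang_mk$sagittal[i_mk],
               ph$data$roll[i_ph] - off[["sagittal"]], tolerance = 1e-6)
  expect_equal(ang_mk$frontal[i_mk],
               ph$data$pitch[i_ph] - off[["frontal"]], tolerance = 1e-6)
  expect_equal(ang_mk$transverse[i_mk],
               ph$data$azimuth[i_ph] - off[["transverse"]] - 0.05 * t_ph,
               tolerance = 1e-6)
})

test_that("static pose yields gravity-only acceleration and offset passthrough", {
  cfg <- fast_config(seed = 2)
  null_amp <- c(transverse = 0, frontal = 0, sagittal = 0)
  pose <- generate_pose(cfg, "SLS", amplitudes = null_amp, depth = 0,
                        ml_accel_target = 0)
  ph <- render_phone(pose)
  expect_equal(ph$data$ax, rep(9.81, n_samples(ph)), tolerance = 1e-9)
  expect_lt(max(abs(ph$data$ay)), 1e-9)
  expect_lt(max(abs(ph$data$az)), 1e-9)
  expect_equal(ph$data$roll, rep(0, n_samples(ph)))

  ph5 <- render_phone(pose, mounting_offset = c(transverse = 0, frontal = 0,
                                                sagittal = 5))
  expect_equal(ph5$data$roll, rep(5, n_samples(ph5)))
  # gravity reads on the tilted device axes
  expect_equal(ph5$data$ax, rep(9.81 * cos(5 * pi / 180), n_samples(ph5)),
               tolerance = 1e-9)

  ph_lin <- render_phone(pose, include_gravity = FALSE)
  expect_lt(max(abs(ph_lin$data$ax)), 1e-9)
})

test_that("heading drift accumulates at the configured rate", {
  cfg <- fast_config(seed = 2)
  pose <- generate_pose(cfg, "SLS",
                        amplitudes = c(transverse = 0, frontal = 0, sagittal = 0),
                        depth = 0, ml_accel_target = 0)
  ph <- render_phone(pose, heading_drift_rate = 0.05)
  dur <- series_duration(ph)
  expect_equal(ph$data$azimuth[n_samples(ph)] - ph$data$azimuth[1],
               0.05 * dur, tolerance = 1e-9)
})

test_that("a fixed seed reproduces the cohort and its files byte-for-byte", {
  cfg <- fast_config(tasks = "SLS", seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$records[[1]]$markers$data, c2$records[[1]]$markers$data)
  expect_identical(c1$records[[1]]$phone$data, c2$records[[1]]$phone$data)

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort structure counts participants x tasks", {
  cfg <- fast_config(seed = 8)
  co <- simulate_cohort(cfg)
  expect_length(co$records, 2 * 3)
  expect_setequal(unique(vapply(co$records, `[[`, "", "task")),
                  c("SLS", "SD15", "SD20"))
})

test_that("true peak angle draws are centred on the per-task locations", {
  cfg <- sim_config(n_participants = 1, seed = 303)
  set.seed(303)
  draws <- replicate(60, generate_pose(cfg, "SLS")$true_peaks)
  # medians within a few standard errors of the configured centres
  tot_sd <- sqrt(cfg$angle_participant_sd^2 + cfg$angle_task_sd^2)
  for (pl in rownames(draws)) {
    se <- 1.25 * tot_sd[[pl]] / sqrt(60)
    expect_lt(abs(median(draws[pl, ]) - cfg$angle_location["SLS", pl]), 4 * se)
  }
})

test_that("configuration validation rejects impossible protocols", {
  expect_error(sim_config(rep_duration = 0), "rep_duration")
  expect_error(sim_config(squat_depth = c(SLS = -0.1, SD15 = 0.1, SD20 = 0.1)),
               "lowers")
  expect_error(sim_config(marker_noise_sd = -1), "SD")
  expect_error(sim_config(master_rate = 600), "multiple")
  cfg <- fast_config(seed = 1)
  expect_error(generate_pose(cfg, "SLS", depth = -0.1,
                             amplitudes = c(transverse = 0, frontal = 0, sagittal = 0)),
               "lowers|non-negative")
})
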