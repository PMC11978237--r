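triangle_disp <- function(rate = 200, total = 4, t0 = 1, tp = 2, t1 = 3,
                          depth = 0.10) {
  t <- seq(0, total, by = 1 / rate)
  d <- numeric(length(t))
  down <- t >= t0 & t <= tp
  up <- t > tp & t <= t1
  d[down] <- -depth * (t[down] - t0) / (tp - t0)
  d[up] <- -depth * (t1 - t[up]) / (t1 - tp)
  list(t = t, d = d)
}

test_that("a flat displacement yields zero repetitions", {
  marks <- detect_repetitions(rep(0, 1000), 200)
  expect_equal(nrow(marks$reps), 0)
  marks2 <- detect_repetitions(rep(-0.002, 1000) + 1e-4 * sin(1:1000), 200)
  expect_equal(nrow(marks2$reps), 0)
})

test_that("triangular repetition crossings follow interpolation arithmetic", {
  tri <- triangle_disp()
  marks <- detect_repetitions(tri$d, 200)
  expect_equal(nrow(marks$reps), 1)
  # exit threshold 5 mm on a 0.10 m triangle: 5% into each 1 s ramp
  expect_equal(marks$reps$start_time, 1.05, tolerance = 1e-9)
  expect_equal(marks$reps$end_time, 2.95, tolerance = 1e-9)
  expect_equal(rep_duration(marks), 1.90, tolerance = 1e-9)
  expect_equal(marks$reps$peak_time, 2.0, tolerance = 1e-9)
  expect_equal(marks$reps$depth, 0.10, tolerance = 1e-12)
  expect_false(marks$reps$plateau)
})

test_that("a flat-bottomed repetition reports the plateau midpoint as peak", {
  rate <- 200
  t <- seq(0, 5, by = 1 / rate)
  d <- numeric(length(t))
  d[t >= 1 & t < 2] <- -0.10 * (t[t >= 1 & t < 2] - 1)
  d[t >= 2 & t <= 3] <- -0.10
  d[t > 3 & t <= 4] <- -0.10 * (4 - t[t > 3 & t <= 4])
  marks <- detect_repetitions(d, rate)
  expect_equal(nrow(marks$reps), 1)
  expect_true(marks$reps$plateau)
  expect_equal(marks$reps$peak_time, 2.5, tolerance = 1 / rate)
})

test_that("generator plateau poses exercise the plateau-midpoint rule", {
  cfg <- fast_config(plateau_fraction = 0.3, seed = 31)
  pose <- generate_pose(cfg, "SLS",
                        amplitudes = c(transverse = -5, frontal = 3, sagittal = 4),
                        depth = 0.15, ml_accel_target = 0)
  kin <- process_mocap(render_mocap(pose, noise_sd = 0))
  marks <- segment_recording(kin, 5)
  expect_equal(nrow(marks$reps), 5)
  expect_true(all(marks$reps$plateau))
  expect_equal(marks$reps$peak_time, pose$events$peak, tolerance = 0.05)
})

test_that("minimum-depth and minimum-duration guards discard non-squats", {
  rate <- 200
  shallow <- triangle_disp(depth = 0.02)    # 20 mm < 30 mm floor
  expect_equal(nrow(detect_repetitions(shallow$d, rate)$reps), 0)
  fast <- triangle_disp(t0 = 1, tp = 1.2, t1 = 1.4)  # 0.4 s < 1 s floor
  expect_equal(nrow(detect_repetitions(fast$d, rate)$reps), 0)
})

test_that("detection is invariant to a constant displacement offset", {
  tri <- triangle_disp()
  m0 <- detect_repetitions(tri$d, 200, baseline_value = 0)
  m1 <- detect_repetitions(tri$d + 0.37, 200, baseline_value = 0.37)
  expect_equal(m0$reps$start_time, m1$reps$start_time)
  expect_equal(m0$reps$end_time, m1$reps$end_time)
  expect_equal(m0$reps$peak_time, m1$reps$peak_time)
})

test_that("baseline search finds the stable window and errors when none", {
  rate <- 100
  t <- seq(0, 8, by = 1 / rate)
  wobble <- ifelse(t < 2.5, 3 * sin(2 * pi * 2 * t), 0)
  kin <- make_kinematics(rate, transverse = wobble + 1, frontal = wobble - 2,
                         sagittal = wobble + 0.5)
  bl <- find_baseline(kin, quiet_duration = 5)
  expect_gt(bl$time, 2.5)   # the quiet second half
  expect_equal(unname(bl$values[["transverse"]]), 1, tolerance = 1e-9)
  expect_equal(unname(bl$values[["frontal"]]), -2, tolerance = 1e-9)

  noisy <- make_kinematics(rate, transverse = 10 * sin(2 * pi * 3 * t))
  expect_error(find_baseline(noisy, quiet_duration = 5), "unstable")

  short <- make_kinematics(rate, transverse = rep(0, 100))
  expect_error(find_baseline(short, quiet_duration = 5), "shorter")
})

test_that("count validation distinguishes strict from permissive", {
  tri <- triangle_disp()
  marks <- detect_repetitions(tri$d, 200)
  expect_silent(m5 <- validate_marks(marks, 1, "strict"))
  expect_false(m5$count_mismatch)
  expect_error(validate_marks(marks, 5, "strict"), "detected 1, expected 5")
  mp <- validate_marks(marks, 5, "permissive")
  expect_true(mp$count_mismatch)
  expect_equal(nrow(mp$reps), 1)
})

test_that("marks order and nesting invariants hold on simulated recordings", {
  cfg <- fast_config(seed = 33)
  co <- simulate_cohort(cfg)
  for (rec in co$records[1:3]) {
    kin <- process_mocap(rec$markers)
    marks <- segment_recording(kin, 5)
    r <- marks$reps
    expect_true(all(r$start_time < r$peak_time & r$peak_time < r$end_time))
    expect_true(all(diff(r$start_time) > 0))
    expect_true(all(r$start_time[-1] >= r$end_time[-nrow(r)]))
    expect_lt(marks$baseline$time, r$start_time[1])
  }
})

test_that("detected durations are shorter than truth by the threshold crossing", {
  cfg <- fast_config(seed = 35, marker_noise_sd = 0)
  for (depth in c(0.08, 0.15, 0.22)) {
    pose <- generate_pose(cfg, "SLS",
                          amplitudes = c(transverse = 0, frontal = 0, sagittal = 0),
                          depth = depth, ml_accel_target = 0)
    kin <- process_mocap(render_mocap(pose, noise_sd = 0))
    marks <- segment_recording(kin, 5)
    durs <- rep_duration(marks)
    expect_true(all(durs < 4))
    # analytic crossing of the exit threshold on the raised cosine
    u <- acos(1 - 2 * 0.005 / depth) / (2 * pi)
    true_detect <- 4 * (1 - 2 * u)
    expect_equal(durs, rep(true_detect, 5), tolerance = 0.03)
  }
})

test_that("marks serialize to JSON and back", {
  tri <- triangle_disp()
  marks <- detect_repetitions(tri$d, 200)
  marks$baseline <- list(index = 10L, time = 0.045,
                         values = c(transverse = 0.1, vertical = 0))
  path <- tempfile(fileext = ".json")
  write_marks_json(marks, path)
  back <- read_marks_json(path)
  expect_equal(back$reps$start_time, marks$reps$start_time)
  expect_equal(back$reps$end_time, marks$reps$end_time)
  expect_equal(back$rate, 200)
  unlink(path)
})
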