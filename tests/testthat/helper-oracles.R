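# Independent oracles and small fixture builders used across the suite.

# Rotation oracle: composes the three basic axis rotations explicitly and
# independently of the package's closed-form matrix entries. Axes:
# 1 = vertical (up), 2 = mediolateral (left), 3 = anteroposterior (anterior).
oracle_rotation <- function(transverse, frontal, sagittal) {
  a <- transverse * pi / 180
  b <- frontal * pi / 180
  cc <- sagittal * pi / 180
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(a), -sin(a)),
              c(0, sin(a), cos(a)))      # about vertical
  Rz <- rbind(c(cos(b), -sin(b), 0),
              c(sin(b), cos(b), 0),
              c(0, 0, 1))                # about anteroposterior
  Ry <- rbind(c(cos(-cc), 0, sin(-cc)),
              c(0, 1, 0),
              c(-sin(-cc), 0, cos(-cc))) # about mediolateral, tilt-positive
  Rx %*% Rz %*% Ry
}

# Two-way mean-squares ICC oracle via stats::aov on the long table.
oracle_icc <- function(x, y) {
  n <- length(x)
  long <- data.frame(y = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(consistency = (msr - mse) / msr,
       absolute = (msr - mse) / (msr + (msc - mse) / n))
}

# Small, fast simulation config for pipeline tests.
fast_config <- function(...) {
  sim_config(n_participants = 2, ...)
}

# Build a pelvic_kinematics series directly from channel vectors.
make_kinematics <- function(rate, transverse, frontal = transverse,
                            sagittal = transverse,
                            vertical = rep(0, length(transverse)),
                            mediolateral = rep(0, length(transverse)),
                            ml_accel = rep(0, length(transverse)),
                            source = "mocap") {
  kin <- uniform_series(data.frame(
    transverse = transverse, frontal = frontal, sagittal = sagittal,
    vertical = vertical, mediolateral = mediolateral, ml_accel = ml_accel),
    rate = rate)
  kin$source <- source
  class(kin) <- c("pelvic_kinematics", "uniform_series")
  kin
}

# Marks with a single repetition at given times (for outcome-formula tests).
make_marks <- function(rate, start, peak, end, baseline_values) {
  structure(list(
    reps = data.frame(start_time = start, peak_time = peak, end_time = end,
                      start_index = round(start * rate) + 1L,
                      peak_index = round(peak * rate) + 1L,
                      end_index = round(end * rate) + 1L,
                      depth = NA_real_, plateau = FALSE),
    rate = rate, baseline_value = baseline_values[["vertical"]],
    baseline = list(index = 1L, time = 0, values = baseline_values),
    expected_reps = NULL, count_mismatch = FALSE),
    class = "repetition_marks")
}

baseline_zero <- c(transverse = 0, frontal = 0, sagittal = 0,
                   vertical = 0, mediolateral = 0, ml_accel = 0)
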