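test_that("both ICC forms match the brute-force two-way ANOVA oracle", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    x <- rnorm(n, 0, sample(c(0.5, 2, 5), 1))
    y <- x + rnorm(n, sample(c(-1, 0, 2), 1), sample(c(0.2, 1), 1))
    or <- oracle_icc(x, y)
    expect_equal(icc_average(x, y, "consistency")$est, or$consistency,
                 tolerance = 1e-10)
    expect_equal(icc_average(x, y, "absolute")$est, or$absolute,
                 tolerance = 1e-10)
  }
})

test_that("a constant offset leaves consistency at 1 and lowers absolute agreement", {
  x <- c(3.2, 5.1, 4.4, 6.0, 2.8, 5.5, 4.9, 3.7)
  y <- x + 1.3
  ic <- icc_average(x, y, "consistency")
  expect_identical(ic$est, 1)
  expect_identical(ic$lower, 1)
  ia <- icc_average(x, y, "absolute")
  expect_lt(ia$est, 1)
  expect_equal(ia$est, oracle_icc(x, y)$absolute, tolerance = 1e-10)

  # identical raters: both forms exactly 1
  ii <- icc_average(x, x, "absolute")
  expect_identical(ii$est, 1)

  # and adding a constant to one rater never changes the consistency form
  set.seed(63)
  x2 <- rnorm(10); y2 <- x2 + rnorm(10, 0, 0.3)
  expect_equal(icc_average(x2, y2 + 5, "consistency")$est,
               icc_average(x2, y2, "consistency")$est, tolerance = 1e-12)
  expect_lt(icc_average(x2, y2 + 5, "absolute")$est,
            icc_average(x2, y2, "absolute")$est)
})

test_that("zero between-participant variance gives an explicit degenerate ICC", {
  x <- rep(2, 6); y <- rep(4, 6)  # every row mean identical
  ic <- icc_average(x, y, "consistency")
  expect_true(ic$degenerate)
  expect_true(is.na(ic$est))
})

test_that("ICC confidence intervals bracket the estimate and match the exact pivot", {
  set.seed(65)
  x <- rnorm(12, 0, 2); y <- x + rnorm(12, 0, 0.8)
  for (m in c("consistency", "absolute")) {
    ic <- icc_average(x, y, m)
    expect_lte(ic$lower, ic$est)
    expect_gte(ic$upper, ic$est)
  }
  # consistency bounds from the F pivot directly
  ic <- icc_average(x, y, "consistency")
  n <- 12; fobs <- ic$msr / ic$mse
  expect_equal(ic$lower, 1 - stats::qf(0.975, n - 1, n - 1) / fobs,
               tolerance = 1e-12)
})

test_that("ICC categories follow the lower-bound rule with stated boundaries", {
  expect_equal(classify_icc(0.91), "excellent")
  expect_equal(classify_icc(0.65), "moderate")
  expect_equal(classify_icc(0.75), "good")
  expect_equal(classify_icc(0.90), "good")
  expect_equal(classify_icc(0.49), "poor")
  expect_equal(classify_icc(-2.3), "poor")
  expect_equal(classify_icc(0.50), "moderate")
  expect_true(is.na(classify_icc(NA)))
  expect_error(classify_icc(1.2), "exceed")
})

test_that("the bias gate selects the right test and handles degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  bt <- test_bias(x, x)
  expect_equal(bt$test, "degenerate")
  expect_equal(bt$bias, 0)
  expect_true(is.na(bt$p))

  set.seed(67)
  mo <- rnorm(52, 10, 1)
  bt2 <- test_bias(mo, mo - rnorm(52, 0.1, 0.05))
  expect_equal(bt2$test, "paired t")
  expect_lt(bt2$p, 0.001)

  # heavy-tailed differences route to the signed-rank test in most samples
  # (Shapiro-Wilk's power against t2 at n = 52 is 0.879, so expect ~88 of 100)
  set.seed(69)
  d_sel <- replicate(100, {
    base <- rnorm(52, 5, 1)
    test_bias(base + stats::rt(52, df = 2) * 0.2, base)$test
  })
  expect_gte(mean(d_sel == "wilcoxon signed-rank"), 0.8)
})

test_that("Bland-Altman reproduces the hand-computed example", {
  y <- c(10, 20, 30)
  x <- y + c(1, 2, 3)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_lower, 2 - 1.96, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 2 + 1.96, tolerance = 1e-12)

  ba0 <- bland_altman(y, y)
  expect_equal(c(ba0$bias, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
})

test_that("Bland-Altman detects proportional bias and its limits cover ~95%", {
  set.seed(71)
  m <- rnorm(200, 10, 3)
  x <- m + 0.15 * m + rnorm(200, 0, 0.5)
  y <- m - 0.15 * m + rnorm(200, 0, 0.5)
  ba <- bland_altman(x, y)
  expect_equal(ba$prop_slope, 0.3, tolerance = 0.1)
  expect_lt(ba$prop_slope_p, 0.01)

  set.seed(73)
  xn <- rnorm(2000, 5, 1); yn <- xn + rnorm(2000, 0.3, 0.7)
  ban <- bland_altman(xn, yn)
  inside <- mean(ban$differences >= ban$loa_lower &
                 ban$differences <= ban$loa_upper)
  expect_gt(inside, 0.935)
  expect_lt(inside, 0.965)
})

test_that("the agreement report has the full outcome x task structure", {
  set.seed(75)
  participants <- sprintf("P%02d", 1:10)
  base <- expand.grid(participant = participants,
                      task = c("SLS", "SD15", "SD20"),
                      stringsAsFactors = FALSE)
  mo <- cbind(base, source = "mocap",
              duration = rnorm(30, 3.4, 0.3),
              ml_accel_sd = rnorm(30, 0.17, 0.03),
              transverse = rnorm(30, -3, 4), frontal = rnorm(30, 2, 3),
              sagittal = rnorm(30, 2, 5))
  ph <- mo; ph$source <- "phone"
  rep_dup <- build_agreement_report(rbind(mo, ph))
  expect_s3_class(rep_dup, "agreement_report")
  expect_equal(nrow(rep_dup), 15)
  expect_true(all(rep_dup$icc == 1))
  expect_true(all(rep_dup$bias_test == "degenerate"))
  expect_true(all(rep_dup$ba_bias == 0))

  # drift flag: transverse rows lose the flagged participant, others keep it
  ph2 <- ph
  ph2$duration <- ph$duration - rnorm(30, 0.15, 0.05)
  ph2$drift_fail <- ph2$participant == "P03" & ph2$task == "SD20"
  rep2 <- build_agreement_report(rbind(cbind(mo, drift_fail = FALSE), ph2))
  tr <- rep2[rep2$outcome == "transverse" & rep2$task == "SD20", ]
  expect_equal(tr$n, 9)
  expect_equal(tr$n_excluded, 1)
  expect_equal(rep2[rep2$outcome == "duration" & rep2$task == "SD20", "n"], 10)
  # the induced duration bias is picked up by the gate -> consistency model
  dur_rows <- rep2[rep2$outcome == "duration", ]
  expect_true(all(dur_rows$p_bias < 0.05))
  expect_true(all(dur_rows$icc_model == "consistency"))

  expect_error(build_agreement_report(mo[, 1:4]), "lacks columns")
})

test_that("increasing phone-side noise monotonically degrades the ICC", {
  set.seed(77)
  participants <- sprintf("P%02d", 1:12)
  truth <- rnorm(12, 0, 4)
  icc_at <- vapply(c(0, 1, 3), function(s) {
    mean(replicate(10, {
      x <- truth + rnorm(12, 0, 0.2)
      y <- truth + rnorm(12, 0, 0.2 + s)
      icc_average(x, y, "absolute")$est
    }))
  }, numeric(1))
  expect_true(all(diff(icc_at) < 0))
})
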