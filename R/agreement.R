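#' Normality-gated paired bias test
#'
#' Tests for a systematic difference between the two measurement systems:
#' Shapiro-Wilk on the paired differences decides between the paired t test
#' (normal) and the Wilcoxon signed-rank test (non-normal; zero differences
#' dropped per the standard definition). All-zero differences give a
#' degenerate result with bias 0 and no p value.
#'
#' @param x,y paired values (x = motion capture, y = smartphone, so a
#'   positive bias means the smartphone reads lower).
#' @param alpha significance level of the normality gate (default 0.05).
#' @return list with `test` ("paired t", "wilcoxon signed-rank" or
#'   "degenerate"), `statistic`, `p`, `bias` (mean difference),
#'   `median_bias`, `normality_p`, `n`.
#' @export
test_bias <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs")
  out <- list(bias = mean(d), median_bias = stats::median(d), n = n)
  if (all(d == 0)) {
    out$test <- "degenerate"
    out$statistic <- NA_real_
    out$p <- NA_real_
    out$normality_p <- NA_real_
    return(out)
  }
  sw <- tryCatch(stats::shapiro.test(d), error = function(e) NULL)
  out$normality_p <- if (is.null(sw)) NA_real_ else sw$p.value
  normal <- !is.null(sw) && sw$p.value >= alpha
  if (normal) {
    tt <- stats::t.test(d)
    out$test <- "paired t"
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    out$test <- "wilcoxon signed-rank"
    out$statistic <- unname(wt$statistic)
    out$p <- wt$p.value
  }
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented motion capture minus smartphone. Bias is the mean
#' difference; the 95% limits of agreement are bias +- 1.96 times the sample
#' SD of the differences. A proportional-bias slope (ordinary least squares
#' of difference on pair mean) is also returned, since acceleration
#' differences in this setting typically grow with the measured magnitude.
#'
#' @param x,y paired values (x = motion capture, y = smartphone).
#' @return list with `bias`, `loa_lower`, `loa_upper`, `sd_diff`,
#'   `prop_slope`, `prop_slope_p`, `n`, and the `differences` and `means`.
#' @export
bland_altman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  m <- (x[ok] + y[ok]) / 2
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs")
  s <- stats::sd(d)
  slope <- NA_real_; slope_p <- NA_real_
  if (stats::sd(m) > 0 && s > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    # perfectly linear differences make the fit exact; the warning is moot
    slope_p <- suppressWarnings(summary(fit)$coefficients[2, 4])
  } else if (s == 0) {
    slope <- 0
  }
  list(bias = mean(d), loa_lower = mean(d) - 1.96 * s,
       loa_upper = mean(d) + 1.96 * s, sd_diff = s,
       prop_slope = slope, prop_slope_p = slope_p, n = n,
       differences = d, means = m)
}

outcome_families <- c("transverse", "frontal", "sagittal", "ml_accel_sd",
                      "duration")

#' Build the full agreement report
#'
#' One row per outcome family x task (3 orientation planes + mediolateral
#' acceleration variability + duration, each for SLS/SD15/SD20 = 15 rows
#' with the default three tasks), each carrying the normality-gated bias
#' test, the average-measures ICC with confidence interval and category, and
#' the Bland-Altman bias and limits of agreement. The ICC model per row
#' follows the bias gate: a significant bias selects the consistency form,
#' otherwise absolute agreement (`icc_model` overrides the gate). Recordings
#' flagged by the heading-drift QC are excluded from the transverse rows of
#' their task, with the exclusion count reported.
#'
#' @param outcomes long data.frame of per-task outcomes: columns participant,
#'   task, source ("mocap"/"phone"), duration, ml_accel_sd, transverse,
#'   frontal, sagittal, and optionally drift_fail (logical).
#' @param alpha significance level of the bias gate.
#' @param icc_model `"gate"` (default), or force `"consistency"`/`"absolute"`.
#' @param conf ICC confidence level.
#' @return data.frame of class `agreement_report`.
#' @export
build_agreement_report <- function(outcomes, alpha = 0.05,
                                   icc_model = c("gate", "consistency", "absolute"),
                                   conf = 0.95) {
  icc_model <- match.arg(icc_model)
  need <- c("participant", "task", "source", outcome_families)
  missing_cols <- setdiff(need, names(outcomes))
  if (length(missing_cols))
    stop("outcome table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"drift_fail" %in% names(outcomes)) outcomes$drift_fail <- FALSE
  tasks <- unique(outcomes$task)
  rows <- list()
  pairs <- list()
  for (fam in outcome_families) {
    for (task in tasks) {
      sub <- outcomes[outcomes$task == task, ]
      excl <- 0L
      if (fam == "transverse") {
        bad <- unique(sub$participant[sub$drift_fail])
        excl <- length(bad)
        sub <- sub[!sub$participant %in% bad, ]
      }
      mo <- sub[sub$source == "mocap", ]
      ph <- sub[sub$source == "phone", ]
      common <- intersect(mo$participant, ph$participant)
      x <- mo[[fam]][match(common, mo$participant)]
      y <- ph[[fam]][match(common, ph$participant)]
      n <- sum(stats::complete.cases(x, y))
      row_id <- paste(fam, task, sep = ".")
      if (n < 3L) {
        rows[[row_id]] <- data.frame(
          outcome = fam, task = task, n = n, n_excluded = excl,
          bias_test = "not-computable", statistic = NA_real_, p_bias = NA_real_,
          bias = NA_real_, icc_model = NA_character_, icc = NA_real_,
          icc_lower = NA_real_, icc_upper = NA_real_,
          icc_category = NA_character_, ba_bias = NA_real_,
          loa_lower = NA_real_, loa_upper = NA_real_,
          prop_slope = NA_real_)
        next
      }
      bt <- test_bias(x, y, alpha)
      model <- if (icc_model == "gate") {
        if (!is.na(bt$p) && bt$p < alpha) "consistency" else "absolute"
      } else icc_model
      ic <- icc_average(x, y, model = model, conf = conf)
      ba <- bland_altman(x, y)
      rows[[row_id]] <- data.frame(
        outcome = fam, task = task, n = n, n_excluded = excl,
        bias_test = bt$test, statistic = bt$statistic, p_bias = bt$p,
        bias = bt$bias, icc_model = model, icc = ic$est,
        icc_lower = ic$lower, icc_upper = ic$upper,
        icc_category = classify_icc(ic$lower), ba_bias = ba$bias,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        prop_slope = ba$prop_slope)
      pairs[[row_id]] <- data.frame(participant = common, mocap = x, phone = y)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "pairs") <- pairs
  class(report) <- c("agreement_report", "data.frame")
  report
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Agreement between motion capture and smartphone\n")
  show <- x[c("outcome", "task", "n", "bias_test", "p_bias", "icc_model",
              "icc", "icc_lower", "icc_upper", "icc_category", "ba_bias",
              "loa_lower", "loa_upper")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], function(col) signif(col, digits))
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Bland-Altman panels of an agreement report
#'
#' One panel per requested outcome/task row: paired differences (motion
#' capture minus smartphone) against pair means, with the bias (solid) and
#' 95% limits of agreement (dashed).
#'
#' @param x an `agreement_report`.
#' @param outcome,task optional filters (defaults: all rows with stored pairs).
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, outcome = NULL, task = NULL, ...) {
  pairs <- attr(x, "pairs")
  keep <- names(pairs)
  if (!is.null(outcome))
    keep <- keep[vapply(strsplit(keep, ".", fixed = TRUE), `[[`, "", 1) %in% outcome]
  if (!is.null(task))
    keep <- keep[vapply(strsplit(keep, ".", fixed = TRUE), `[[`, "", 2) %in% task]
  if (!length(keep)) stop("no stored pairs match the filter")
  nk <- length(keep)
  oldpar <- graphics::par(mfrow = c(ceiling(nk / 3), min(nk, 3)),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (id in keep) {
    p <- pairs[[id]]
    d <- p$mocap - p$phone
    m <- (p$mocap + p$phone) / 2
    row <- x[paste(x$outcome, x$task, sep = ".") == id, ]
    graphics::plot(m, d, xlab = "pair mean", ylab = "mocap - phone",
                   main = id, ...)
    graphics::abline(h = row$ba_bias, lwd = 2)
    graphics::abline(h = c(row$loa_lower, row$loa_upper), lty = 2)
  }
  invisible(x)
}
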