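#' Two-way average-measures intraclass correlation
#'
#' ICC of the mean of k = 2 measurement systems from the two-way mean
#' squares (rows = participants, columns = systems). With MSR, MSC, MSE the
#' row, column and error mean squares and n participants:
#'
#' \deqn{ICC(C,k) = (MSR - MSE) / MSR}
#' \deqn{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#'
#' The consistency form ignores a systematic offset between the systems; the
#' absolute-agreement form penalises it. 95% confidence bounds use the exact
#' F pivot for the consistency form and the Satterthwaite-approximated F for
#' absolute agreement (the standard two-way mixed-effects formulas), with the
#' single-measures bounds stepped up to average measures by Spearman-Brown.
#'
#' @param x,y paired per-participant values of the two systems (same length,
#'   pairwise complete).
#' @param model `"consistency"` or `"absolute"`.
#' @param conf confidence level (default 0.95).
#' @return list with `model`, `est`, `lower`, `upper`, `n`, `k`, the mean
#'   squares, and `degenerate` (TRUE when between-participant variance is
#'   zero and the ICC is undefined).
#' @export
icc_average <- function(x, y, model = c("absolute", "consistency"),
                        conf = 0.95) {
  model <- match.arg(model)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs for an ICC")
  k <- 2L
  grand <- mean(c(x, y))
  rowm <- (x + y) / 2
  colm <- c(mean(x), mean(y))
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- (sum((x - rowm - colm[1] + grand)^2) +
            sum((y - rowm - colm[2] + grand)^2)) / ((n - 1) * (k - 1))
  out <- list(model = model, n = n, k = k, msr = msr, msc = msc, mse = mse,
              degenerate = FALSE)
  if (msr <= .Machine$double.eps * (mse + msc + 1)) {
    # no between-participant variance: ICC undefined
    out$degenerate <- TRUE
    out$est <- out$lower <- out$upper <- NA_real_
    return(out)
  }
  alpha <- 1 - conf
  if (mse == 0) {
    # both systems identical up to (for consistency) a constant
    if (model == "consistency" || msc == 0) {
      out$est <- out$lower <- out$upper <- 1
    } else {
      out$est <- (msr - mse) / (msr + (msc - mse) / n)
      out$lower <- out$upper <- out$est
    }
    return(out)
  }
  if (model == "consistency") {
    out$est <- (msr - mse) / msr
    fobs <- msr / mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    out$lower <- 1 - 1 / (fobs / stats::qf(1 - alpha / 2, df1, df2))
    out$upper <- 1 - 1 / (fobs * stats::qf(1 - alpha / 2, df2, df1))
  } else {
    out$est <- (msr - mse) / (msr + (msc - mse) / n)
    # single-measures absolute-agreement bounds (Satterthwaite df), then
    # Spearman-Brown step-up to average measures
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    fj <- msc / mse
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * fj + b)^2 / (a^2 * fj^2 / (k - 1) + b^2 / (n - 1))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    out$lower <- low1 * k / (1 + (k - 1) * low1)
    out$upper <- up1 * k / (1 + (k - 1) * up1)
  }
  out
}

#' Agreement category from the ICC confidence bound
#'
#' Categories applied to the lower bound of the ICC confidence interval:
#' below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to 0.9 good, above 0.9
#' excellent.
#'
#' @param ci_lower lower confidence bound (at most 1; the F-based bound can
#'   fall below -1 for weak agreement at small n, which is still "poor").
#' @return one of "poor", "moderate", "good", "excellent".
#' @export
classify_icc <- function(ci_lower) {
  if (is.na(ci_lower)) return(NA_character_)
  if (ci_lower > 1) stop("`ci_lower` cannot exceed 1")
  if (ci_lower < 0.5) "poor"
  else if (ci_lower < 0.75) "moderate"
  else if (ci_lower <= 0.9) "good"
  else "excellent"
}
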