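#' Butterworth filter specification
#'
#' The three filters the analysis uses are all zero-phase Butterworth designs:
#' a 4th-order 10 Hz low-pass for orientation channels, a 4th-order 1 Hz
#' high-pass for acceleration channels, and a 2nd-order 0.1 Hz high-pass used
#' at each step of the accelerometer double integration to suppress drift.
#' Filtering is always applied forward-backward (two passes) so events keep
#' their timing; a one-pass IIR filter would delay peaks and bias the
#' peak-window outcomes.
#'
#' @param kind `"low"` or `"high"`.
#' @param order filter order (>= 1); the order of one pass.
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency
#'   of any series the spec is applied to.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("low", "high"), order, cutoff) {
  kind <- match.arg(kind)
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order))
    stop("`order` must be a positive integer")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("`cutoff` must be a single positive number (Hz)")
  structure(list(kind = kind, order = as.integer(order), cutoff = cutoff),
            class = "filter_spec")
}

# One forward pass of an IIR filter with steady-state initial conditions:
# the filter state is initialised as if the input had been constant at x[1]
# forever, so a constant input produces its exact steady-state output from
# sample one (no start-up transient).
iir_filter_ss <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  h1 <- sum(b) / sum(a)  # DC gain
  x0 <- x[1]
  u <- stats::filter(c(rep(x0, nb - 1L), x), b, sides = 1)
  u <- as.numeric(u)[-seq_len(nb - 1L)]
  if (na > 1L) {
    as.numeric(stats::filter(u, -a[-1], method = "recursive",
                             init = rep(h1 * x0, na - 1L)))
  } else {
    u
  }
}

#' Zero-phase Butterworth filtering of one channel
#'
#' Forward-backward application of a Butterworth filter (coefficients from
#' [signal::butter()]). The signal is extended at both ends by odd reflection
#' before filtering, with the extension length scaled to the filter time
#' constant (3/cutoff seconds), and each pass starts from steady-state initial
#' conditions. This keeps edge transients out of the retained samples even for
#' the very low 0.1 Hz drift cutoff; a constant input is reproduced exactly
#' (low-pass) or zeroed exactly (high-pass).
#'
#' @param x numeric vector.
#' @param rate sampling rate of `x` in Hz.
#' @param spec a [filter_spec()].
#' @return filtered numeric vector, same length as `x`.
#' @export
apply_filter <- function(x, rate, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 spec$cutoff, rate / 2))
  bf <- signal::butter(spec$order, spec$cutoff / (rate / 2),
                       type = if (spec$kind == "low") "low" else "high")
  n <- length(x)
  npad <- min(n - 1L, max(30L, ceiling(3 * rate / spec$cutoff)))
  i <- seq_len(npad)
  ext <- c(2 * x[1] - x[npad + 2L - i], x, 2 * x[n] - x[n - i])
  y <- iir_filter_ss(bf$b, bf$a, ext)
  y <- rev(iir_filter_ss(bf$b, bf$a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

# Cumulative trapezoidal integral with zero initial condition.
cumtrapz_dt <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}
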