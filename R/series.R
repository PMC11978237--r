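#' Uniformly sampled multichannel series
#'
#' The basic in-memory container shared by every stage of the pipeline: a set
#' of equally long, gap-free channels sampled on a uniform time grid. Marker
#' trajectories (250 Hz), smartphone logs (100 Hz), ground-truth poses and
#' processed kinematics are all stored this way.
#'
#' @param data data.frame (or coercible) of numeric channels, one column each.
#' @param rate sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds.
#' @param units optional named character vector of channel units.
#' @return an object of class `uniform_series`.
#' @export
uniform_series <- function(data, rate, start = 0, units = NULL) {
  data <- as.data.frame(data)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (ncol(data) < 1L || nrow(data) < 2L)
    stop("a uniform series needs at least one channel of length >= 2")
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("all channels must be numeric")
  structure(
    list(data = data, rate = rate, start = start, units = units),
    class = "uniform_series"
  )
}

#' Time axis of a uniform series
#' @param series a `uniform_series`.
#' @return numeric vector of sample times in seconds.
#' @export
series_time <- function(series) {
  series$start + (seq_len(nrow(series$data)) - 1L) / series$rate
}

#' Number of samples
#' @param series a `uniform_series`.
#' @export
n_samples <- function(series) nrow(series$data)

#' Duration in seconds (last minus first sample time)
#' @param series a `uniform_series`.
#' @export
series_duration <- function(series) (n_samples(series) - 1L) / series$rate

#' Extract one channel as a numeric vector
#' @param series a `uniform_series`.
#' @param name channel (column) name.
#' @export
series_channel <- function(series, name) {
  if (!name %in% names(series$data))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(series$data), collapse = ", ")))
  series$data[[name]]
}

#' Decimate a uniform series by an integer factor
#'
#' Exact sample-dropping decimation (no interpolation): the master-rate
#' simulation grid is chosen so both sensor rates divide it, which keeps the
#' two rendered branches sample-aligned with the ground truth.
#'
#' @param series a `uniform_series`.
#' @param factor positive integer decimation factor.
#' @export
decimate_series <- function(series, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  if (factor == 1L) return(series)
  keep <- seq(1L, nrow(series$data), by = factor)
  out <- series
  out$data <- series$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out$rate <- series$rate / factor
  out
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz (%.2f s), %d channel(s)\n",
              n_samples(x), x$rate, series_duration(x), ncol(x$data)))
  cat("  channels:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}
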