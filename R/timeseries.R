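#' Uniformly sampled time series
#'
#' Lightweight container used for all waveform data in the package: probe
#' force (N), segmented vessel areas (mm^2), and pressures (mmHg). Samples are
#' uniformly spaced; the time base is `t0 + (i - 1) / sample_rate`.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units Unit tag, e.g. `"mmHg"`, `"N"`, `"mm2"`.
#' @return An object of class `qcu_ts`.
#' @export
qcu_ts <- function(values, sample_rate, t0 = 0, units = "") {
  values <- as.numeric(values)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series values must be finite")
  structure(
    list(values = values, sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0), units = as.character(units)),
    class = "qcu_ts"
  )
}

#' @export
print.qcu_ts <- function(x, ...) {
  cat(sprintf("<qcu_ts> %d samples @ %g Hz, t = [%.3f, %.3f] s%s\n",
              length(x$values), x$sample_rate, x$t0,
              x$t0 + (length(x$values) - 1) / x$sample_rate,
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

#' @export
length.qcu_ts <- function(x) length(x$values)

#' @export
mean.qcu_ts <- function(x, ...) mean(x$values, ...)

#' @export
as.data.frame.qcu_ts <- function(x, ...) {
  data.frame(t = ts_time(x), value = x$values)
}

#' Sample times of a time series
#'
#' @param x A [qcu_ts] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "qcu_ts"))
  x$t0 + (seq_along(x$values) - 1L) / x$sample_rate
}

#' Extract a time window from a time series
#'
#' @param x A [qcu_ts] object.
#' @param from,to Window limits in seconds (inclusive).
#' @return A [qcu_ts] holding the samples with `from <= t <= to`.
#' @export
ts_window <- function(x, from = -Inf, to = Inf) {
  tt <- ts_time(x)
  keep <- tt >= from & tt <= to
  if (!any(keep)) stop("empty time window")
  qcu_ts(x$values[keep], x$sample_rate, t0 = tt[which(keep)[1]],
         units = x$units)
}

# Shift a series in time by an integer number of samples, padding with the
# edge values so length and time base are preserved.
ts_shift_samples <- function(x, k) {
  v <- x$values
  n <- length(v)
  k <- as.integer(round(k))
  out <- if (k == 0) v
  else if (k > 0) c(rep(v[1], min(k, n)), v)[seq_len(n)]
  else c(v, rep(v[n], min(-k, n)))[-seq_len(min(-k, n))]
  qcu_ts(out, x$sample_rate, x$t0, x$units)
}
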