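#' Separate cardiac from respiratory variation
#'
#' Physiological waveforms recorded here mix two bands: cardiac-cycle
#' variation (period < 1 s, right-atrial a/c/x/v/y morphology) and
#' respiratory variation (period > 1 s, roughly sinusoidal). `split_bands`
#' separates them with a zero-phase low-pass at `cutoff_hz`: the low-passed
#' series (mean retained) is the respiratory component and the residual is
#' the cardiac component, so `respiratory + cardiac` reconstructs the input
#' exactly.
#'
#' The filter is applied in the frequency domain with a Butterworth-magnitude
#' gain `1 / sqrt(1 + (f / fc)^(2 * order))` and zero phase; the series is
#' reflection-padded before transforming to suppress edge effects. With the
#' default order, content at 1.2 times the cutoff is attenuated by more than
#' 90 percent while content at a quarter of the cutoff passes within 0.1
#' percent.
#'
#' @param x A [qcu_ts].
#' @param cutoff_hz Cardiac/respiratory boundary in Hz. Default 1, i.e. a 1 s
#'   period.
#' @param order Butterworth-magnitude order of the gain curve.
#' @return A `band_split` list: `respiratory` and `cardiac` ([qcu_ts]) and
#'   `cutoff_hz`.
#' @export
split_bands <- function(x, cutoff_hz = 1.0, order = 8) {
  stopifnot(inherits(x, "qcu_ts"))
  n <- length(x$values)
  if (n < 3 * x$sample_rate / cutoff_hz)
    stop("series too short to separate bands: need at least ",
         "3 / cutoff_hz seconds")
  low <- fft_lowpass(x$values, x$sample_rate, cutoff_hz, order)
  resp <- qcu_ts(low, x$sample_rate, x$t0, x$units)
  card <- qcu_ts(x$values - low, x$sample_rate, x$t0, x$units)
  structure(list(respiratory = resp, cardiac = card, cutoff_hz = cutoff_hz),
            class = "band_split")
}

# Zero-phase low-pass: odd (point-symmetric) reflection padding + FFT-domain
# Butterworth-magnitude gain. Zero phase holds by construction (real, even
# gain); odd reflection keeps both value and slope continuous at the edges.
fft_lowpass <- function(v, fs, cutoff_hz, order) {
  n <- length(v)
  pad <- min(n - 1, ceiling(3 * fs / cutoff_hz))
  left <- 2 * v[1] - v[pad + 1]
  if (pad > 1) left <- 2 * v[1] - v[(pad + 1):2]
  right <- 2 * v[n] - v[n - 1]
  if (pad > 1) right <- 2 * v[n] - v[(n - 1):(n - pad)]
  ext <- c(left, v, right)
  m <- length(ext)
  f <- seq(0, m - 1) / m * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  # two-pass (forward-backward) Butterworth power response: zero phase with
  # the squared magnitude of an order-`order` filter, as filtfilt would give
  gain <- 1 / (1 + (f / cutoff_hz)^(2 * order))
  out <- Re(stats::fft(stats::fft(ext) * gain, inverse = TRUE)) / m
  out[pad + seq_len(n)]
}

#' Standard deviation attributed to respiratory variation
#'
#' Filters out the cardiac-cycle band and returns the standard deviation of
#' the respiratory component about its mean, in the input's units. For a pure
#' respiratory sinusoid of amplitude A this is A / sqrt(2).
#'
#' @param x A [qcu_ts].
#' @param cutoff_hz Cardiac/respiratory boundary in Hz, passed to
#'   [split_bands()].
#' @return Scalar standard deviation in the units of `x`.
#' @export
respiratory_sd <- function(x, cutoff_hz = 1.0) {
  bands <- split_bands(x, cutoff_hz = cutoff_hz)
  stats::sd(bands$respiratory$values)
}

#' Time offset between force and area channels from sync compressions
#'
#' QCU acquisitions bracket the protocol with two quick probe compressions;
#' these appear as sharp spikes in the force channel and sharp dips in the
#' vessel-area channel and are used to synchronize the two data streams.
#' The offset is found as the lag maximizing the cross-correlation between
#' the transient (high-pass) band of the force and the negated transient band
#' of the area.
#'
#' @param force Force channel, a [qcu_ts] in N.
#' @param area Vessel-area channel, a [qcu_ts] in mm^2, same sample rate.
#' @param max_lag_s Largest |offset| searched, s.
#' @param transient_cutoff_hz High-pass boundary isolating the quick
#'   compressions from the slow ramp/hold profile.
#' @return Offset in seconds such that `area` lags `force` by the returned
#'   amount (positive offset: area events occur later in its own time base).
#' @export
detect_sync_offset <- function(force, area, max_lag_s = 5,
                               transient_cutoff_hz = 2) {
  stopifnot(inherits(force, "qcu_ts"), inherits(area, "qcu_ts"))
  if (abs(force$sample_rate - area$sample_rate) > 1e-9)
    stop("force and area must share a sample rate")
  fs <- force$sample_rate
  ft <- transient_band(force$values, fs, transient_cutoff_hz)
  at <- -transient_band(area$values, fs, transient_cutoff_hz)
  if (count_transients(ft, fs) < 2 || count_transients(at, fs) < 2)
    stop("unsyncable capture: fewer than two detectable sync transients")
  # keep only the neighbourhood of the force spikes so that slow-channel
  # structure (ramp collapse, respiratory reopening) cannot win the match,
  # and compress amplitudes so one giant excursion cannot outweigh the
  # joint alignment of both sync compressions
  ft <- ft * transient_mask(ft, fs)
  ft <- sign(ft) * sqrt(abs(ft))
  at <- sign(at) * sqrt(abs(at))
  max_lag <- min(round(max_lag_s * fs),
                 length(ft) - 1L, length(at) - 1L)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) lagged_dot(ft, at, k), numeric(1))
  lags[which.max(cc)] / fs
}

transient_band <- function(v, fs, cutoff_hz) {
  v - fft_lowpass(v, fs, cutoff_hz, order = 4)
}

# 0/1 mask covering +-pad_s around every high-prominence excursion
transient_mask <- function(v, fs, prominence = 6, pad_s = 0.5) {
  scale <- stats::mad(v)
  if (scale == 0) scale <- stats::sd(v)
  if (scale == 0) return(rep(0, length(v)))
  hot <- which(abs(v) > prominence * scale)
  mask <- rep(0, length(v))
  pad <- round(pad_s * fs)
  for (i in hot)
    mask[max(1, i - pad):min(length(v), i + pad)] <- 1
  mask
}

# number of well-separated high-prominence transients
count_transients <- function(v, fs, prominence = 6, min_sep_s = 1) {
  scale <- stats::mad(v)
  if (scale == 0) scale <- stats::sd(v)
  if (scale == 0) return(0L)
  hot <- which(abs(v) > prominence * scale)
  if (length(hot) == 0) return(0L)
  sum(diff(c(-Inf, hot)) > min_sep_s * fs)
}

# dot product of x(t) with y(t + k) over the overlapping support
lagged_dot <- function(x, y, k) {
  n <- min(length(x), length(y))
  if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k])
  else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)])
}
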