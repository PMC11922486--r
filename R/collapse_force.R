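#' IJV occlusion threshold
#'
#' Complete occlusion of the vein's short-axis cross-section is declared when
#' the segmented area dips below 0.5 mm^2.
#' @export
OCCLUSION_THRESHOLD_MM2 <- 0.5

#' Extract the collapse force from a synchronized capture
#'
#' The collapse force (CF) is the minimum probe force that completely
#' occludes the short-axis cross-section of the vein. It is read off the
#' force ramp as the force at the first ramp sample where the segmented IJV
#' area drops below the occlusion threshold ("first crossing": CF is a
#' minimum, so ties break toward the earlier time).
#'
#' @param capture A `qcu_capture` with aligned force and area channels (see
#'   [sync_capture()]) and a ramp phase.
#' @param threshold_mm2 Occlusion threshold, mm^2.
#' @return A `collapse_estimate`: `cf` (N), `collapse_time` (s),
#'   `threshold_mm2`, with the uncertainty bounds `cf_lo` / `cf_hi` unset
#'   until [cf_uncertainty()] fills them.
#' @export
find_collapse_force <- function(capture, threshold_mm2 = OCCLUSION_THRESHOLD_MM2) {
  stopifnot(inherits(capture, "qcu_capture"))
  ramp <- which(capture$phase == "ramp")
  if (length(ramp) == 0) stop("capture has no ramp phase")
  area <- capture$ijv_area$values[ramp]
  force <- capture$force$values[ramp]
  if (area[1] < threshold_mm2)
    stop("pre-collapsed: vein already occluded at ramp start")
  below <- which(area < threshold_mm2)
  if (length(below) == 0)
    stop("no collapse detected: area never dips below ", threshold_mm2,
         " mm2 during ramp")
  hit <- below[1]
  structure(list(cf = force[hit], cf_lo = NA_real_, cf_hi = NA_real_,
                 collapse_time = ts_time(capture$force)[ramp[hit]],
                 threshold_mm2 = threshold_mm2),
            class = "collapse_estimate")
}

#' @export
print.collapse_estimate <- function(x, ...) {
  cat(sprintf("Collapse force: %.3f N at t = %.2f s (threshold %.2g mm2)\n",
              x$cf, x$collapse_time, x$threshold_mm2))
  if (!is.na(x$cf_lo))
    cat(sprintf("  uncertainty: [%.3f, %.3f] N\n", x$cf_lo, x$cf_hi))
  invisible(x)
}

#' Collapse-force uncertainty from near-collapse area variation
#'
#' Cardiac and respiratory variation make the IJV area waveform oscillate
#' while the ramp passes through collapse, so a range of forces could
#' plausibly have been the first to occlude the vein: troughs of the area
#' waveform touch the occlusion threshold before its peaks do. The minimum
#' feasible collapse force is where the waveform's lower envelope crosses
#' the threshold — by the first-crossing convention this is the measured
#' collapse force itself, which is trough-aligned. The maximum feasible
#' collapse force is where the upper envelope crosses: the first ramp force
#' from which the area stays occluded, i.e. just past the last reopening
#' above the threshold on the ascending ramp. If the waveform peaks still
#' reopen the vein when the ascending ramp ends, the upper-envelope
#' crossing is linearly extrapolated from the trend of the per-cycle area
#' maxima over the near-collapse window, and clipped to the observed
#' ramp-force range with a warning.
#'
#' @param capture The `qcu_capture` the estimate came from.
#' @param estimate A `collapse_estimate` from [find_collapse_force()].
#' @param window_s Length of the near-collapse window used when the
#'   upper-envelope crossing must be extrapolated, s.
#' @param cycle_s Chunk length used to pick per-cycle extrema; should be on
#'   the order of (and not shorter than half) a cardiac period.
#' @return The `collapse_estimate` with `cf_lo` and `cf_hi` filled.
#' @export
cf_uncertainty <- function(capture, estimate, window_s = 4, cycle_s = 0.5) {
  stopifnot(inherits(capture, "qcu_capture"),
            inherits(estimate, "collapse_estimate"))
  t <- ts_time(capture$force)
  ramp <- capture$phase == "ramp"
  # ascending part of the ramp only (the phase label also covers the release)
  ramp_idx <- which(ramp)
  peak <- ramp_idx[which.max(capture$force$values[ramp_idx])]
  ascending <- which(ramp & seq_along(t) <= peak)
  fs <- capture$sample_rate
  per_chunk <- max(2L, round(cycle_s * fs))
  post <- ascending[t[ascending] >= estimate$collapse_time]
  if (length(post) < per_chunk)
    stop("window too short to form area envelopes")
  area <- capture$ijv_area$values
  force <- capture$force$values
  thr <- estimate$threshold_mm2
  f_ramp_max <- force[peak]

  open <- post[area[post] >= thr]
  if (length(open) == 0) {
    hi <- estimate$cf                     # occlusion is immediately sustained
  } else if (max(open) < max(post)) {
    hi <- force[max(open) + 1L]           # first force of sustained occlusion
  } else {
    # peaks reopen through the end of the ramp: extrapolate the per-cycle
    # maxima trend over the near-collapse window to the threshold
    win <- ascending[t[ascending] >= estimate$collapse_time - window_s / 2]
    chunk <- (seq_along(win) - 1L) %/% per_chunk
    a_max <- tapply(area[win], chunk, max)
    f_at <- tapply(force[win], chunk, function(f) f[length(f)])
    m <- length(a_max)
    hi <- if (m < 2 || a_max[m] >= a_max[m - 1]) NA_real_
    else f_at[m] + (thr - a_max[m]) * (f_at[m] - f_at[m - 1]) /
      (a_max[m] - a_max[m - 1])
    if (is.na(hi) || hi > f_ramp_max) {
      warning("upper envelope crossing beyond the ramp force range; clipped")
      hi <- f_ramp_max
    }
  }
  estimate$cf_lo <- estimate$cf
  estimate$cf_hi <- max(hi, estimate$cf)
  estimate
}
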