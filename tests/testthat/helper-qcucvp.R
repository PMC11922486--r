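# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# cardiac-free waveform spec: bumps disabled, respiration/noise default off
flat_cvp_spec <- function(mean_cvp = 5, resp_amplitude = 0, noise_sd = 0,
                          ...) {
  cvp_waveform_spec(mean_cvp = mean_cvp, resp_amplitude = resp_amplitude,
                    noise_sd = noise_sd, amp_a = 0, amp_c = 0, amp_v = 0,
                    amp_x = 0, amp_y = 0, ...)
}

std_capture <- function() {
  cached("std_capture", function() synth_capture(5, 30, seed = 7))
}

# one ramp sample's worth of force, N
ramp_force_increment <- function(protocol = capture_protocol()) {
  (protocol$ramp_peak - protocol$base_force) /
    (protocol$ramp_s * protocol$sample_rate)
}

hold_truth <- function(capture) {
  idx <- which(capture$phase == "hold")
  qcu_ts(capture$truth$cvp$values[idx], capture$sample_rate,
         t0 = ts_time(capture$force)[idx[1]], units = "mmHg")
}
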