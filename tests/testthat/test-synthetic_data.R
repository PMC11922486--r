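test_that("CVP waveform generator honours its spec", {
  # all variation disabled: constant series at the mean
  w0 <- synth_cvp_waveform(flat_cvp_spec(mean_cvp = 7))
  expect_true(all(w0$values == 7))

  # pure respiratory sinusoid: closed-form mean and range
  # (28 s = 7 full respiratory cycles at 15 breaths/min)
  w <- synth_cvp_waveform(flat_cvp_spec(mean_cvp = 5, resp_amplitude = 2,
                                        duration = 28))
  expect_equal(mean(w$values), 5, tolerance = 1e-6)
  expect_equal(diff(range(w$values)), 4, tolerance = 1e-3)

  # seeded determinism
  spec <- cvp_waveform_spec(seed = 42)
  expect_identical(synth_cvp_waveform(spec)$values,
                   synth_cvp_waveform(spec)$values)

  # cardiac morphology leaves the time mean at the requested level
  wm <- synth_cvp_waveform(cvp_waveform_spec(mean_cvp = 4, noise_sd = 0,
                                             resp_amplitude = 0))
  expect_equal(mean(wm$values), 4, tolerance = 1e-9)

  expect_error(cvp_waveform_spec(resp_rate = 70), "period > 1 s")
  expect_error(cvp_waveform_spec(duration = 1), "2 cardiac cycles")
  expect_error(cvp_waveform_spec(heart_rate = -10), "positive")
})

test_that("cardiac and respiratory band energies match the generating spec", {
  base <- list(mean_cvp = 5, noise_sd = 0, duration = 40, seed = 1)
  full <- synth_cvp_waveform(do.call(cvp_waveform_spec,
                                     c(base, resp_amplitude = 2)))
  resp_only <- synth_cvp_waveform(do.call(flat_cvp_spec,
                                          c(base, resp_amplitude = 2)))
  card_only <- synth_cvp_waveform(do.call(cvp_waveform_spec,
                                          c(base, resp_amplitude = 0)))
  bands <- split_bands(full)
  expect_equal(stats::var(bands$respiratory$values),
               stats::var(resp_only$values), tolerance = 0.1)
  expect_equal(stats::var(bands$cardiac$values),
               stats::var(card_only$values), tolerance = 0.1)
})

test_that("capture generator produces a physical, deterministic protocol", {
  cap <- std_capture()
  expect_true(all(cap$force$values >= 0))
  expect_true(all(cap$ijv_area$values >= 0))
  expect_setequal(unique(cap$phase),
                  c("pre", "sync_spike", "ramp", "hold", "post"))

  # ramp force non-decreasing up to its maximum
  rf <- cap$force$values[cap$phase == "ramp"]
  upto <- seq_len(which.max(rf))
  expect_true(all(diff(rf[upto]) >= 0))

  # the ramp drives the vein through occlusion
  expect_lt(min(cap$ijv_area$values[cap$phase == "ramp"]),
            OCCLUSION_THRESHOLD_MM2)

  # determinism
  cap2 <- synth_capture(5, 30, seed = 7)
  expect_identical(cap$ijv_area$values, cap2$ijv_area$values)
  expect_identical(cap$force$values, cap2$force$values)

  # never-occluding protocol is rejected
  expect_error(synth_capture(5, 30, protocol = capture_protocol(ramp_peak = 2)),
               "never reaches occlusion")
})

test_that("monotone tube law: ramp area is non-increasing in force", {
  cap <- synth_capture(5, 30, cvp_spec = flat_cvp_spec(),
                       vessel = vessel_params(kappa = 0))
  ramp <- cap$phase == "ramp"
  rf <- cap$force$values[ramp]
  # stop short of the ramp peak: the segmentation smoothing window there
  # blends in the release-phase reopening
  upto <- seq_len(which.max(rf) - 10)
  area <- cap$ijv_area$values[ramp][upto]
  expect_true(all(diff(area) <= 1e-6))
})

test_that("collapse requires surface pressure beyond the venous pressure", {
  cap <- synth_capture(5, 30, cvp_spec = flat_cvp_spec(),
                       vessel = vessel_params(kappa = 0, transmission = 1))
  p_at_cf <- probe_pressure(cap$truth$cf, cap$vessel)
  expect_gt(p_at_cf, 5)  # needs a negative transmural margin on top of CVP
})

test_that("ground-truth collapse force increases with true mean CVP", {
  shape <- cvp_waveform_spec(mean_cvp = 5, noise_sd = 0, seed = 3)
  cf <- vapply(c(2, 4, 6, 8, 10), function(m)
    synth_capture(m, 30, cvp_spec = shape)$truth$cf, numeric(1))
  expect_true(all(diff(cf) > 0))
})

test_that("synthetic cohorts are reproducible and span the requested range", {
  coh <- cached("cohort_s4", function() synth_cohort(11, seed = 4))
  expect_equal(nrow(coh$table), 11)
  expect_length(coh$captures, 11)
  expect_gt(diff(range(coh$table$avg_invasive_cvp_mmhg)), 5)
  expect_true(all(coh$table$cf_n > 0))
  expect_true(all(coh$table$ho_cmh2o >= 0))

  coh2 <- synth_cohort(11, seed = 4)
  expect_equal(coh2$table$cf_n, coh$table$cf_n)
  expect_equal(coh2$table$jvp_mmhg, coh$table$jvp_mmhg)

  expect_error(synth_cohort(1), "n_subjects")
  expect_warning(
    synth_cohort(3, population = list(mean_cvp_range = c(5, 5)),
                 seed = 1),
    "zero-variance")
})
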