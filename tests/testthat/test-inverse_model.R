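test_that("forward model honours the tube-law limits", {
  v <- vessel_params()
  # zero transmural pressure: unstressed area
  p_ext0 <- probe_pressure(2, v)  # kappa term vanishes at the reference
  out <- forward_areas(p_ext0, v$carotid_p_ref, 2, v)
  expect_equal(out$ijv_area, v$a_ref, tolerance = 1e-6)

  # crushing force: complete occlusion
  out <- forward_areas(5, v$carotid_p_ref, 100, v)
  expect_lt(out$ijv_area, 0.5)

  # kappa = 0 decouples the IJV from carotid pressure
  v0 <- vessel_params(kappa = 0)
  a1 <- forward_areas(5, 80, 2, v0)$ijv_area
  a2 <- forward_areas(5, 130, 2, v0)$ijv_area
  expect_equal(a1, a2)
  # and the carotid follows its linear compliance
  expect_equal(forward_areas(5, 90, 2, v0)$carotid_area,
               v0$carotid_a_ref + 10 * v0$carotid_compliance)

  expect_error(forward_areas(5, 80, -1, v), ">= 0")
})

test_that("forward areas are monotone in pressure and force", {
  v <- vessel_params()
  p_grid <- seq(-4, 20, length.out = 30)
  a <- vapply(p_grid, function(p)
    forward_areas(p, 80, 2, v)$ijv_area, numeric(1))
  expect_true(all(diff(a) > 0))

  f_grid <- seq(0, 12, length.out = 30)
  a <- vapply(f_grid, function(f)
    forward_areas(5, 80, f, v)$ijv_area, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("frame inversion is the forward model's inverse", {
  v <- vessel_params()
  # unstressed area with no probe force and no coupling: ambient pressure
  v0 <- vessel_params(kappa = 0)
  sol <- invert_frame(v0$a_ref, 80, 0, v0)
  expect_true(sol$converged)
  expect_equal(sol$p_ijv, 0, tolerance = 0.05)

  # round trip over random operating points
  set.seed(5)
  for (i in 1:300) {
    p <- runif(1, -4, 35)
    f <- runif(1, 0, 10)
    pc <- runif(1, 70, 130)
    a <- forward_areas(p, pc, f, v)$ijv_area
    sol <- invert_frame(a, pc, f, v)
    expect_true(sol$converged)
    # compare in area space (the collapsed branch is pressure-insensitive)
    expect_lte(abs(forward_areas(sol$p_ijv, pc, f, v)$ijv_area - a),
               1e-3 * v$a_ref)
  }

  # unattainable area: flagged, not extrapolated
  big <- forward_areas(40, 80, 0, v)$ijv_area + 5
  expect_false(invert_frame(big, 80, 0, v)$converged)
})

test_that("waveform reconstruction recovers the generating CVP", {
  cap <- cached("cap_inverse", function()
    synth_capture(5, 30, seed = 11, cvp_noise_sd = 0))
  truth <- hold_truth(cap)
  res <- estimate_cvp_waveform(cap, anchor_cvp = mean(truth$values))
  expect_equal(res$anchor_mean, mean(truth$values), tolerance = 0.1)
  rmse <- sqrt(mean((res$cvp_waveform$values - truth$values)^2))
  expect_lt(rmse / diff(range(truth$values)), 0.05)
  expect_equal(res$converged_frames, length(truth$values))
  expect_lt(max(res$per_frame_residual), 1e-3 * cap$vessel$a_ref + 1e-9)
})

test_that("constant inputs reconstruct a constant waveform at the anchor", {
  cap <- synth_capture(5, 30, cvp_spec = flat_cvp_spec(),
                       vessel = vessel_params(kappa = 0))
  res <- estimate_cvp_waveform(cap, anchor_cvp = 5)
  # interior frames: the first/last instants blend into the neighbouring
  # phases through the segmentation smoothing window
  interior <- res$cvp_waveform$values[100:(length(res$cvp_waveform$values) - 100)]
  expect_lt(diff(range(interior)), 1e-6)
  expect_equal(res$anchor_mean, 5, tolerance = 0.01)
})

test_that("carotid coupling raises the reconstructed v peak", {
  v <- vessel_params(kappa = 0.05)
  cap <- synth_capture(5, 30, vessel = v,
                       cvp_spec = cvp_waveform_spec(mean_cvp = 5,
                                                    resp_amplitude = 0,
                                                    noise_sd = 0),
                       seed = 3)
  truth <- hold_truth(cap)
  anchor <- mean(truth$values)
  with_k <- estimate_cvp_waveform(cap, anchor_cvp = anchor)
  no_k <- estimate_cvp_waveform(cap, anchor_cvp = anchor,
                                vessel = vessel_params(kappa = 0))

  # peak ratio (v wave vs a/c waves) using the known beat timing
  peak_ratio <- function(w) {
    t <- ts_time(w)
    phase <- (t * 75 / 60) %% 1
    base <- min(w$values)
    v_pk <- max(w$values[phase > 0.55 & phase < 0.75])
    ac_pk <- max(w$values[phase > 0.02 & phase < 0.35])
    (v_pk - base) / (ac_pk - base)
  }
  expect_gt(peak_ratio(with_k$cvp_waveform), peak_ratio(no_k$cvp_waveform))
})

test_that("observation noise does not inflate the recovered amplitude", {
  spec <- cvp_waveform_spec(mean_cvp = 5, noise_sd = 0, seed = 9)
  noisy <- synth_capture(5, 30, cvp_spec = spec,
                         protocol = capture_protocol(area_noise_sd = 0.3),
                         seed = 9)
  truth <- hold_truth(noisy)
  res <- estimate_cvp_waveform(noisy, anchor_cvp = mean(truth$values))
  expect_lte(stats::sd(res$cvp_waveform$values), stats::sd(truth$values))
})

test_that("reconstruction fails loudly on unusable inputs", {
  cap <- cached("cap_inverse", function()
    synth_capture(5, 30, seed = 11, cvp_noise_sd = 0))
  # anchor below the hold-phase external pressure is inconsistent
  expect_error(estimate_cvp_waveform(cap, anchor_cvp = 0.2),
               "mean-anchoring failed")
  # a pressure bracket that excludes most frames
  expect_error(
    estimate_cvp_waveform(cap, anchor_cvp = mean(hold_truth(cap)$values),
                          bracket = c(4.99, 5.01)),
    "unconverged|no frame")
  # hold phase must be near-constant force
  wobble <- cap
  hold <- which(wobble$phase == "hold")
  wobble$force$values[hold] <- wobble$force$values[hold] +
    seq(0, 2, length.out = length(hold))
  expect_error(estimate_cvp_waveform(wobble,
                                     anchor_cvp = mean(hold_truth(cap)$values)),
               "near-constant")
})
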