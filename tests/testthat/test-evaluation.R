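degenerate_collapse <- function(cf) {
  structure(list(cf = cf, cf_lo = cf, cf_hi = cf, collapse_time = 10,
                 threshold_mm2 = 0.5), class = "collapse_estimate")
}

spread_collapse <- function(cf, lo, hi) {
  structure(list(cf = cf, cf_lo = lo, cf_hi = hi, collapse_time = 10,
                 threshold_mm2 = 0.5), class = "collapse_estimate")
}

test_that("method intervals compose measurement uncertainties as specified", {
  tab <- qcu_study_table()
  fit_cf <- fit_linear(tab, "CF")
  fit_ch <- fit_linear(tab, c("CF", "HO"))

  # JVP: fixed 0.5 mmHg in each direction
  iv <- method_interval("JVP", tab[2, ])
  expect_equal(c(iv$lo, iv$center, iv$hi), c(3.18, 3.68, 4.18))

  # degenerate collapse interval maps to a zero-width CF interval
  est <- degenerate_collapse(tab$cf_n[3])
  iv_cf <- method_interval("CF", tab[3, ], est, fit_cf)
  expect_equal(iv_cf$hi - iv_cf$lo, 0)
  expect_equal(iv_cf$center, unname(predict(fit_cf, tab[3, ])))

  # CF+HO inherits the mapped CF width plus 0.5 mmHg on each side
  est2 <- spread_collapse(5, 4.5, 5.5)
  r <- tab[3, ]; r$cf_n <- 5
  w_cf <- with(method_interval("CF", r, est2, fit_cf), hi - lo)
  w_ch <- with(method_interval("CF_HO", r, est2, fit_ch), hi - lo)
  slope_ratio <- fit_ch$coefficients["CF"] / fit_cf$coefficients["CF"]
  expect_equal(w_ch, w_cf * unname(slope_ratio) + 1, tolerance = 1e-9)

  # trained-model interval also carries the hydrostatic padding
  iv_tm <- method_interval("TrainedModel", r, est2)
  expect_equal(iv_tm$hi - iv_tm$lo, 0.42 * 1 + 1, tolerance = 1e-9)

  expect_error(method_interval("CF", tab[3, ], fit = fit_cf),
               "collapse estimate")
  expect_error(method_interval("JVP", tab[1, ]), "no measured JVP")
})

test_that("invasive interval spans two respiratory standard deviations", {
  cst <- qcu_ts(rep(5, 2000), 100)
  iv <- invasive_interval(cst)
  expect_equal(c(iv$lo, iv$center, iv$hi), c(5, 5, 5))

  t <- (0:2999) / 100
  resp <- qcu_ts(5 + 2 * sin(2 * pi * 0.25 * t), 100)
  iv <- invasive_interval(resp)
  expect_equal(iv$hi - iv$lo, 4 * 2 / sqrt(2), tolerance = 0.1)
  expect_equal(iv$center, 5, tolerance = 0.05)

  expect_error(invasive_interval(qcu_ts(rep(5, 100), 100)), "too short")

  # the subject with the most respiratory variation has the widest interval
  amps <- c(0.5, 1.5, 3)
  widths <- vapply(amps, function(a) {
    w <- synth_cvp_waveform(cvp_waveform_spec(resp_amplitude = a,
                                              noise_sd = 0))
    with(invasive_interval(w), hi - lo)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("JVP overlap accuracy on the study table is 1/8", {
  tab <- qcu_study_table()
  ivs <- stats::setNames(lapply(seq_len(nrow(tab)), function(i)
    if (tab$jvp_status[i] == "measured") method_interval("JVP", tab[i, ])
    else NULL), as.character(tab$subject_id))
  rep <- overlap_accuracy("JVP", tab, ivs)
  expect_equal(rep$n_eligible, 5)
  expect_equal(rep$n_forced_misses, 3)
  expect_equal(rep$n_hits, 1)           # only subject 4 (4.0 in [3.18, 4.18])
  expect_equal(rep$accuracy, 0.125)
})

test_that("eligibility rules and accuracy arithmetic hold", {
  tab <- qcu_study_table()
  ids <- as.character(tab$subject_id)
  wide <- stats::setNames(lapply(seq_len(nrow(tab)), function(i)
    qcucvp:::new_interval(5, -1e6, 1e6, "combined")), ids)

  # CF methods exclude the two EJV subjects: denominator 9
  rep <- overlap_accuracy("CF", tab, wide)
  expect_equal(rep$n_eligible, 9)
  expect_equal(rep$accuracy, 1)

  # all-covering intervals hit every eligible subject but not forced misses
  rep <- overlap_accuracy("JVP", tab, wide)
  expect_equal(rep$accuracy, 5 / 8)

  # zero-width intervals far from the truth never hit
  far <- stats::setNames(lapply(ids, function(i)
    qcucvp:::new_interval(-99, -99, -99, "combined")), ids)
  expect_equal(overlap_accuracy("CF", tab, far)$accuracy, 0)

  expect_error(overlap_accuracy("CF", tab, wide[1:3]), "missing interval")
})

test_that("widening an interval never converts a hit into a miss", {
  tab <- qcu_study_table()
  ids <- as.character(tab$subject_id)
  set.seed(3)
  centers <- tab$avg_invasive_cvp_mmhg + rnorm(11, 0, 2)
  for (grow in c(1, 2, 5)) {
    base <- stats::setNames(lapply(seq_len(11), function(i)
      qcucvp:::new_interval(centers[i], centers[i] - 0.5, centers[i] + 0.5,
                            "combined")), ids)
    wide <- stats::setNames(lapply(seq_len(11), function(i)
      qcucvp:::new_interval(centers[i], centers[i] - 0.5 * grow,
                            centers[i] + 0.5 * grow, "combined")), ids)
    expect_gte(overlap_accuracy("CF", tab, wide)$accuracy,
               overlap_accuracy("CF", tab, base)$accuracy)
  }
})
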