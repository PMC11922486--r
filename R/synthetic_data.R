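# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic central venous pressure waveform
#'
#' Describes a right-atrial pressure waveform as a mean level plus per-beat
#' cardiac morphology, sinusoidal respiratory modulation, and white
#' measurement noise. The cardiac morphology is a train of smooth Gaussian
#' bumps per beat: the positive a (atrial contraction), c (tricuspid
#' closure), and v (atrial filling) waves and the negative x (atrial
#' relaxation) and y (passive emptying) descents, at fixed intra-beat phase
#' offsets with the v wave placed in ventricular systole. The bump train is
#' centred so the waveform's time mean equals `mean_cvp` (up to noise and
#' partial respiratory cycles).
#'
#' @param mean_cvp Mean pressure, mmHg.
#' @param heart_rate Beats per minute (> 0).
#' @param resp_rate Breaths per minute; must be < 60 so the respiratory
#'   period exceeds 1 s.
#' @param resp_amplitude Peak amplitude of the respiratory sinusoid, mmHg.
#' @param amp_a,amp_c,amp_v Peak heights of the positive waves, mmHg.
#' @param amp_x,amp_y Depths (positive numbers) of the descents, mmHg.
#' @param noise_sd Gaussian noise SD, mmHg.
#' @param duration Length in seconds; must cover at least 2 cardiac cycles.
#' @param sample_rate Hz.
#' @param seed Optional integer seed making generation deterministic.
#' @return A `cvp_waveform_spec` list.
#' @export
cvp_waveform_spec <- function(mean_cvp = 5, heart_rate = 75, resp_rate = 15,
                              resp_amplitude = 1.5, amp_a = 1.5, amp_c = 0.8,
                              amp_v = 1.8, amp_x = 1.2, amp_y = 1.0,
                              noise_sd = 0.2, duration = 30,
                              sample_rate = 100, seed = NULL) {
  if (heart_rate <= 0 || resp_rate <= 0 || duration <= 0 || sample_rate <= 0)
    stop("rates, duration and sample_rate must be positive")
  if (resp_rate >= 60)
    stop("resp_rate must be < 60 breaths/min (respiratory period > 1 s)")
  if (duration * heart_rate / 60 < 2)
    stop("duration must cover at least 2 cardiac cycles")
  structure(list(mean_cvp = mean_cvp, heart_rate = heart_rate,
                 resp_rate = resp_rate, resp_amplitude = resp_amplitude,
                 amp_a = amp_a, amp_c = amp_c, amp_v = amp_v,
                 amp_x = amp_x, amp_y = amp_y, noise_sd = noise_sd,
                 duration = duration, sample_rate = sample_rate, seed = seed),
            class = "cvp_waveform_spec")
}

# Intra-beat phase centres and widths (fractions of the cardiac period) of
# the five wave components. v sits in ventricular systole.
CVP_WAVE_PHASE <- c(a = 0.10, c = 0.25, x = 0.42, v = 0.65, y = 0.85)
CVP_WAVE_WIDTH <- c(a = 0.050, c = 0.040, x = 0.070, v = 0.070, y = 0.060)

# Periodic Gaussian bump train over beat phase in [0, 1).
beat_morphology <- function(phase, amps) {
  signs <- c(a = 1, c = 1, x = -1, v = 1, y = -1)
  out <- numeric(length(phase))
  for (w in names(CVP_WAVE_PHASE)) {
    d <- abs(phase - CVP_WAVE_PHASE[[w]])
    d <- pmin(d, 1 - d)
    out <- out + signs[[w]] * amps[[w]] * exp(-0.5 * (d / CVP_WAVE_WIDTH[[w]])^2)
  }
  out
}

#' Generate a synthetic CVP waveform
#'
#' @param spec A [cvp_waveform_spec].
#' @return A [qcu_ts] in mmHg, deterministic for a given `spec$seed`.
#' @examples
#' w <- synth_cvp_waveform(cvp_waveform_spec(mean_cvp = 5, noise_sd = 0,
#'                                           resp_amplitude = 0, amp_a = 0,
#'                                           amp_c = 0, amp_v = 0, amp_x = 0,
#'                                           amp_y = 0))
#' all(w$values == 5)
#' @export
synth_cvp_waveform <- function(spec) {
  stopifnot(inherits(spec, "cvp_waveform_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  phase <- (t * spec$heart_rate / 60) %% 1
  amps <- list(a = spec$amp_a, c = spec$amp_c, x = spec$amp_x,
               v = spec$amp_v, y = spec$amp_y)
  cardiac <- beat_morphology(phase, amps)
  cardiac <- cardiac - mean(cardiac)
  resp <- spec$resp_amplitude * sin(2 * pi * t * spec$resp_rate / 60)
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  else numeric(n)
  qcu_ts(spec$mean_cvp + cardiac + resp + noise, spec$sample_rate,
         units = "mmHg")
}

#' Simplified carotid pressure waveform
#'
#' Two-level per-beat pulse highlighting end-diastole and peak-systole: a
#' square-ish pulse at the systolic level over the stated phase window,
#' smoothed at the transitions, riding on the diastolic level. The systolic
#' window overlaps the v wave of the venous waveform, as carotid systole
#' coincides with atrial filling.
#'
#' @param heart_rate Beats/min.
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @param p_dia,p_sys Diastolic and systolic levels, mmHg.
#' @param systole Phase window (fractions of the beat) held at `p_sys`.
#' @param transition Phase width of the smooth transitions.
#' @return A [qcu_ts] in mmHg.
#' @export
synth_carotid_pressure <- function(heart_rate = 75, duration = 30,
                                   sample_rate = 100, p_dia = 80,
                                   p_sys = 120, systole = c(0.55, 0.85),
                                   transition = 0.05) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  phase <- (t * heart_rate / 60) %% 1
  sstep <- function(z) {
    z <- pmin(pmax(z, 0), 1)
    3 * z^2 - 2 * z^3
  }
  pulse <- sstep((phase - systole[1]) / transition) *
    (1 - sstep((phase - systole[2]) / transition))
  qcu_ts(p_dia + (p_sys - p_dia) * pulse, sample_rate, units = "mmHg")
}

#' Acquisition protocol for a synthetic QCU capture
#'
#' Timeline (all durations in seconds): a low-force pre segment containing
#' the first quick sync compression, a linear force ramp up to `ramp_peak`
#' (past occlusion), a quick release, a constant-force hold with the vein
#' lightly compressed, and a post segment containing the closing sync
#' compression.
#'
#' @param sample_rate Hz.
#' @param base_force Resting probe force, N.
#' @param pre_s,ramp_s,release_s,hold_s,post_s Segment durations.
#' @param ramp_peak Peak ramp force, N; must exceed the subject's collapse
#'   force for occlusion to occur.
#' @param hold_force Constant hold force, N.
#' @param spike_force Added force of each sync compression, N.
#' @param spike_width_s Half-width of the triangular sync compressions.
#' @param lag_s Artificial time lag applied to the area channels (emulating
#'   unsynchronized force and imaging streams); recoverable with
#'   [detect_sync_offset()].
#' @param area_noise_sd Gaussian noise added to the observed areas, mm^2.
#' @param area_smooth_s Moving-average window applied to the observed areas,
#'   emulating the temporal regularity of segmentation output.
#' @return A `capture_protocol` list.
#' @export
capture_protocol <- function(sample_rate = 100, base_force = 0.5,
                             pre_s = 2, ramp_s = 30, release_s = 1,
                             hold_s = 14, post_s = 2, ramp_peak = 15,
                             hold_force = 1, spike_force = 12,
                             spike_width_s = 0.15, lag_s = 0,
                             area_noise_sd = 0, area_smooth_s = 0.05) {
  stopifnot(sample_rate > 0, base_force >= 0, ramp_peak > base_force,
            hold_force >= 0, spike_force > 0, spike_width_s > 0)
  structure(list(sample_rate = sample_rate, base_force = base_force,
                 pre_s = pre_s, ramp_s = ramp_s, release_s = release_s,
                 hold_s = hold_s, post_s = post_s, ramp_peak = ramp_peak,
                 hold_force = hold_force, spike_force = spike_force,
                 spike_width_s = spike_width_s, lag_s = lag_s,
                 area_noise_sd = area_noise_sd,
                 area_smooth_s = area_smooth_s),
            class = "capture_protocol")
}

moving_average <- function(v, k) {
  if (k <= 1) return(v)
  kern <- rep(1 / k, k)
  n <- length(v)
  padded <- c(rep(v[1], k), v, rep(v[n], k))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[k + seq_len(n)])
}

#' Generate a complete synthetic QCU capture
#'
#' Builds the force profile of [capture_protocol()], drives the
#' collapsible-tube forward model ([forward_areas()]) with a synthetic CVP
#' waveform and a simplified carotid pressure waveform, and returns the
#' synchronized force and per-frame segmented-area channels together with
#' the ground truth. The ground-truth collapse force is the force at the
#' first ramp sample where the modeled (noise-free) IJV area drops below the
#' 0.5 mm^2 occlusion threshold.
#'
#' @param mean_cvp True mean CVP of the subject, mmHg.
#' @param theta_deg Inclination angle, degrees (recorded in the truth block;
#'   it determines the hydrostatic offset, not the compression mechanics).
#' @param vessel A [vessel_params].
#' @param protocol A [capture_protocol].
#' @param cvp_spec Optional [cvp_waveform_spec]; its mean, duration and
#'   sample rate are overridden to match `mean_cvp` and the protocol. By
#'   default, cardiac and respiratory amplitudes are scaled with
#'   `sqrt(mean_cvp / 5)` (a 5 mmHg subject gets the reference amplitudes)
#'   so low-pressure veins carry smaller pulsations without the waveform
#'   ever dipping below zero.
#' @param cvp_noise_sd Gaussian noise SD of the default CVP waveform, mmHg;
#'   ignored when `cvp_spec` is supplied.
#' @param carotid List with `p_dia`, `p_sys` for the carotid waveform.
#' @param seed Optional seed; captures are fully deterministic given a seed.
#' @return A `qcu_capture`: `force`, `ijv_area`, `carotid_area` ([qcu_ts]),
#'   `phase` (per-sample labels in pre / sync_spike / ramp / hold / post),
#'   `sample_rate`, `protocol`, `vessel`, and a `truth` block (`cvp`,
#'   `carotid_pressure`, `cf`, `collapse_time`, `mean_cvp`, `theta_deg`,
#'   `lag_s`).
#' @export
synth_capture <- function(mean_cvp, theta_deg = 30, vessel = vessel_params(),
                          protocol = capture_protocol(), cvp_spec = NULL,
                          cvp_noise_sd = 0.2,
                          carotid = list(p_dia = 80, p_sys = 120),
                          seed = NULL) {
  p <- protocol
  fs <- p$sample_rate
  duration <- p$pre_s + p$ramp_s + p$release_s + p$hold_s + p$post_s
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  # --- force profile and phase labels -------------------------------------
  t_ramp0 <- p$pre_s
  t_ramp1 <- p$pre_s + p$ramp_s
  t_hold0 <- t_ramp1 + p$release_s
  t_hold1 <- t_hold0 + p$hold_s
  force <- rep(p$base_force, n)
  phase <- rep("pre", n)
  in_ramp <- t >= t_ramp0 & t < t_ramp1
  force[in_ramp] <- p$base_force +
    (p$ramp_peak - p$base_force) * (t[in_ramp] - t_ramp0) / p$ramp_s
  phase[in_ramp] <- "ramp"
  in_rel <- t >= t_ramp1 & t < t_hold0
  force[in_rel] <- p$ramp_peak +
    (p$hold_force - p$ramp_peak) * (t[in_rel] - t_ramp1) / p$release_s
  phase[in_rel] <- "ramp"
  in_hold <- t >= t_hold0 & t < t_hold1
  force[in_hold] <- p$hold_force
  phase[in_hold] <- "hold"
  phase[t >= t_hold1] <- "post"
  spikes <- c(p$pre_s / 2, t_hold1 + p$post_s / 2)
  for (tc in spikes) {
    tri <- pmax(0, 1 - abs(t - tc) / p$spike_width_s)
    force <- force + p$spike_force * tri
    phase[abs(t - tc) <= p$spike_width_s] <- "sync_spike"
  }

  # --- true pressures ------------------------------------------------------
  if (is.null(cvp_spec)) {
    scale <- sqrt(mean_cvp / 5)
    cvp_spec <- cvp_waveform_spec(
      mean_cvp = mean_cvp, resp_amplitude = 1.5 * scale,
      amp_a = 1.5 * scale, amp_c = 0.8 * scale, amp_v = 1.8 * scale,
      amp_x = 1.2 * scale, amp_y = 1.0 * scale, noise_sd = cvp_noise_sd,
      duration = duration, sample_rate = fs, seed = seed)
  } else {
    cvp_spec$mean_cvp <- mean_cvp
    cvp_spec$duration <- duration
    cvp_spec$sample_rate <- fs
    if (is.null(cvp_spec$seed)) cvp_spec$seed <- seed
  }
  true_cvp <- synth_cvp_waveform(cvp_spec)
  p_car <- synth_carotid_pressure(cvp_spec$heart_rate, duration, fs,
                                  p_dia = carotid$p_dia,
                                  p_sys = carotid$p_sys)

  # --- forward model -------------------------------------------------------
  fw <- forward_areas(true_cvp$values, p_car$values, force, vessel)
  ijv_clean <- moving_average(fw$ijv_area, round(p$area_smooth_s * fs))
  car_clean <- moving_average(fw$carotid_area, round(p$area_smooth_s * fs))

  ramp_idx <- which(phase == "ramp" & t < t_ramp1)
  below <- ijv_clean[ramp_idx] < OCCLUSION_THRESHOLD_MM2
  if (!any(below))
    stop("protocol never reaches occlusion during ramp; increase ramp_peak")
  hit <- ramp_idx[which(below)[1]]
  truth_cf <- force[hit]
  hold_area <- ijv_clean[in_hold]
  if (stats::median(hold_area) < OCCLUSION_THRESHOLD_MM2)
    stop("hold_force occludes the vein at this mean CVP; lower hold_force")

  ijv_obs <- ijv_clean
  car_obs <- car_clean
  if (p$area_noise_sd > 0) {
    noise <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                       stats::rnorm(2 * n, 0, p$area_noise_sd))
    ijv_obs <- pmax(0, ijv_obs + noise[seq_len(n)])
    car_obs <- pmax(0, car_obs + noise[n + seq_len(n)])
  }
  ijv_ts <- qcu_ts(ijv_obs, fs, units = "mm2")
  car_ts <- qcu_ts(car_obs, fs, units = "mm2")
  if (p$lag_s != 0) {
    k <- round(p$lag_s * fs)
    ijv_ts <- ts_shift_samples(ijv_ts, k)
    car_ts <- ts_shift_samples(car_ts, k)
  }

  structure(list(
    force = qcu_ts(force, fs, units = "N"),
    ijv_area = ijv_ts,
    carotid_area = car_ts,
    phase = phase,
    sample_rate = fs,
    protocol = p,
    vessel = vessel,
    truth = list(cvp = true_cvp, carotid_pressure = p_car, cf = truth_cf,
                 collapse_time = t[hit], mean_cvp = mean_cvp,
                 theta_deg = theta_deg, lag_s = p$lag_s)
  ), class = "qcu_capture")
}

#' @export
print.qcu_capture <- function(x, ...) {
  cat(sprintf("<qcu_capture> %.1f s @ %g Hz; phases: %s\n",
              length(x$force$values) / x$sample_rate, x$sample_rate,
              paste(rle(x$phase)$values, collapse = " > ")))
  if (!is.null(x$truth))
    cat(sprintf("  truth: mean CVP %.2f mmHg, CF %.2f N\n",
                x$truth$mean_cvp, x$truth$cf))
  invisible(x)
}

#' Re-synchronize the area channels of a capture
#'
#' Estimates the force/area time offset from the sync compressions with
#' [detect_sync_offset()] and shifts the area channels so the streams align.
#'
#' @param capture A `qcu_capture`.
#' @return The capture with aligned area channels and the applied offset in
#'   `capture$sync_offset_s`.
#' @export
sync_capture <- function(capture) {
  off <- detect_sync_offset(capture$force, capture$ijv_area)
  k <- round(off * capture$sample_rate)
  capture$ijv_area <- ts_shift_samples(capture$ijv_area, -k)
  capture$carotid_area <- ts_shift_samples(capture$carotid_area, -k)
  capture$sync_offset_s <- off
  capture
}

#' Generate a synthetic study cohort
#'
#' Draws per-subject true mean CVPs and inclination angles, generates one
#' QCU capture per subject, measures the collapse force from the capture,
#' computes the hydrostatic offset from the angle, and derives a bedside JVP
#' reading as the (quantized) height at which the venous column's transmural
#' pressure crosses zero, converted with [jvp_to_mmhg()]. JVP readings whose
#' pulsation height falls outside the visible window at the subject's
#' inclination are recorded as attempted but unmeasurable, mirroring
#' unfavourable inclination angles in practice.
#'
#' @param n_subjects Number of subjects (`>= 2`).
#' @param population List of population distributions: `mean_cvp_range`
#'   (mmHg), `theta_range_deg`, `a_ref_mean` / `a_ref_sd` (mm^2), and
#'   `jvp_visible_cm` (the measurable pulsation-height window).
#' @param vessel Base [vessel_params]; `a_ref` is redrawn per subject.
#' @param protocol A [capture_protocol] shared by all subjects.
#' @param cvp_noise_sd Measurement-noise SD of the per-subject CVP
#'   waveforms, mmHg; set to 0 for a noise-free cohort.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return List with `table` (a [study_table] of measured quantities) and
#'   `captures` (list of `qcu_capture`).
#' @export
synth_cohort <- function(n_subjects = 11,
                         population = list(),
                         vessel = vessel_params(),
                         protocol = capture_protocol(),
                         cvp_noise_sd = 0.2,
                         seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  pop <- utils::modifyList(
    list(mean_cvp_range = c(0.5, 10.5), theta_range_deg = c(15, 40),
         a_ref_mean = 120, a_ref_sd = 8, jvp_visible_cm = c(2, 20)),
    population)
  if (diff(range(pop$mean_cvp_range)) == 0 && n_subjects > 2)
    warning("zero-variance mean_cvp distribution: calibration will be singular")
  draws <- with_seed(seed, list(
    cvp = stats::runif(n_subjects, pop$mean_cvp_range[1], pop$mean_cvp_range[2]),
    theta = stats::runif(n_subjects, pop$theta_range_deg[1],
                         pop$theta_range_deg[2]),
    a_ref = pmax(60, stats::rnorm(n_subjects, pop$a_ref_mean, pop$a_ref_sd))
  ))
  captures <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    v <- vessel
    v$a_ref <- draws$a_ref[i]
    cap <- synth_capture(draws$cvp[i], draws$theta[i], vessel = v,
                         protocol = protocol, cvp_noise_sd = cvp_noise_sd,
                         seed = seed * 1000L + i)
    est <- find_collapse_force(cap)
    theta <- draws$theta[i]
    sin_th <- sin(theta * pi / 180)
    h_cm <- draws$cvp[i] / (C_MMHG_PER_CMH2O * sin_th)
    visible <- h_cm >= pop$jvp_visible_cm[1] & h_cm <= pop$jvp_visible_cm[2]
    jvp <- if (visible) jvp_to_mmhg(round(h_cm * 2) / 2, theta) else NA_real_
    rows[[i]] <- data.frame(
      subject_id = i,
      avg_invasive_cvp_mmhg = mean(cap$truth$cvp$values),
      vein = "LIJ",
      cf_n = est$cf,
      ho_cmh2o = hydrostatic_offset(theta),
      jvp = if (visible) formatC(jvp, format = "f", digits = 4) else "X",
      stringsAsFactors = FALSE)
    captures[[i]] <- cap
  }
  table <- as_study_table(do.call(rbind, rows))
  list(table = table, captures = captures)
}
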