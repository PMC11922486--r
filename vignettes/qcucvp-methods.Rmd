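---
title: "Estimating central venous pressure from compression ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating central venous pressure from compression ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcucvp)
```

## The measurement principle

A vein held open by internal pressure \(P_v\) collapses when the external
pressure on its wall exceeds \(P_v\) by the (small) structural margin the
wall itself contributes. Quantitative compression ultrasound (QCU) exploits
this: the probe presses on the internal jugular vein (IJV) with a measured
force while segmented short-axis images track the lumen area, and the
**collapse force** CF — the minimum force at which the area first drops
below the 0.5 mm² occlusion threshold — is a mechanical surrogate of
central venous pressure (CVP). Calibrated against invasive CVP across a
cohort, CF yields a noninvasive scalar estimate; combined with a
constant-force hold and an inverse mechanical model, it yields an estimate
of the full venous pressure *waveform*.

The package implements four layers: a physiological simulator, signal
processing, the scalar calibration/evaluation chain, and the waveform
inverse model. This vignette records the modelling choices, their defaults,
and what each is meant to capture.

## Collapsible-tube forward model

The paper-grade reference for vessel compression is a 2-D finite-element
simulation. Here the vessel is a *reduced-order collapsible tube*: with
\(\alpha = A/A_{\mathrm{ref}}\) the lumen area normalized by its unstressed
value, the transmural pressure (internal minus external) is

\[ P_{tm}(\alpha) \;=\; k\,(\alpha^{n_+} - \alpha^{-n_-}), \]

which is strictly increasing in \(\alpha\), zero at the unstressed area,
stiffens steeply in distension (\(n_+ = 10\)), and lets the area fall
smoothly to zero under negative transmural pressure (\(n_- = 0.35\)). The
forward surface (`forward_areas()`) is deliberately small so that a
finite-element backend could be substituted behind the same interface.

External pressure on the IJV combines two terms:

* the probe: a uniform surface pressure `transmission * force /
  contact_area`, with `transmission = 0.21` the fraction reaching the
  vessel through the intervening tissue and `contact_area = 15 cm²` a
  large-footprint probe;
* the carotid artery: `kappa * (P_carotid − P_diastolic)` with
  `kappa = 0.02`, representing the systolic push of the pulsating carotid
  on the adjacent vein.

The carotid itself is far stiffer than the vein and is modelled with a
linear compliance (0.15 mm²/mmHg about a 40 mm² reference at diastolic
pressure).

Defaults (`vessel_params()`): \(A_{\mathrm{ref}} = 120\) mm² (a mid-sized
adult IJV), \(k = 0.3\) mmHg. With these, occluding to 0.5 mm² requires
about 2 mmHg of negative transmural pressure on top of the venous pressure,
and a newton of probe force translates to roughly 1.05 mmHg at the vessel
— choices that place simulated collapse forces in the 2–12 N range typical
of adult measurements. None of these constants are fitted to data; they are
stated model choices, and every test that depends on them goes through the
generator so the chain remains self-consistent.

## The synthetic data generator

`synth_cvp_waveform()` builds a right-atrial pressure waveform as

mean + per-beat cardiac morphology + respiratory sinusoid + white noise.

The cardiac morphology is a train of Gaussian bumps per beat — positive a
(atrial contraction, phase 0.10 of the beat), c (tricuspid closure, 0.25),
v (atrial filling, 0.65) and negative x (0.42), y (0.85) — because the
canonical waveform is described qualitatively, not by a formula; the bump
train is centred so the time mean equals the requested mean exactly.
Respiration is additive and sinusoidal (its period must exceed 1 s), which
matches its smoother morphology. Defaults: 75 beats/min, 15 breaths/min,
amplitudes of 1.5/0.8/1.8/1.2/1.0 mmHg for a/c/v/x/y and 1.5 mmHg of
respiratory modulation at a 5 mmHg mean; in `synth_capture()` all
amplitudes scale with \(\sqrt{\text{mean}/5}\) so low-pressure subjects
carry proportionally smaller pulsations and the waveform never goes
negative.

`synth_capture()` assembles a full acquisition at 100 Hz: a 2 s low-force
(0.5 N) pre-phase containing the first quick sync compression, a 30 s
linear ramp to 15 N (a slow, deliberate compression through occlusion), a
1 s release, a 14 s constant-force hold at 1 N with the vein lightly
compressed, and a closing sync compression — about 49 s in all, matching a
roughly one-minute bedside procedure. Sync compressions are triangular
12 N, 0.3 s presses: they must be firm enough to indent the vein at any
plausible CVP, otherwise the area channel carries no matching dip. The
observed areas are smoothed with a 0.05 s moving average (segmentation
output is temporally regular) and optionally carry additive Gaussian noise;
an optional acquisition lag between the force and image streams emulates
the unsynchronized clocks of the two devices. The ground-truth collapse
force is recorded as the force at the first ramp sample where the
noise-free modelled area crosses 0.5 mm².

What the generator does **not** emulate: B-mode image formation and
segmentation failure modes, probe tilt and anatomical variation, vessel
viscoelasticity (the tube law is quasi-static), reflex changes in venous
tone, and any drift in the force sensor. Tests passing on synthetic
captures therefore validate the *analysis logic* under the stated
mechanical model, not robustness to real-world image artefacts.

## Signal processing

Cardiac and respiratory variation are separated at a 1 Hz boundary (the
1 s period that divides the two regimes). The low-pass is implemented in
the frequency domain with the two-pass Butterworth power response
\(1/(1+(f/f_c)^{2n})\), \(n = 8\), applied to an odd-reflection-padded
segment: zero phase holds by construction, content at 1.2 Hz is attenuated
by ~95 % while content at 0.25 Hz passes within 0.1 %, and the odd
(point-symmetric) padding keeps both value and slope continuous at the
edges. A transfer-function filtfilt at a 0.02 relative cutoff would be
numerically fragile, which is why the filter is applied spectrally. The
respiratory standard deviation — used for the invasive uncertainty
interval, mean ± 2 SD — is the SD of the low-passed component about its
mean.

Force–image synchronization cross-correlates the transient (> 2 Hz) band
of the force with the negated transient band of the area. Two safeguards
matter in practice: the force transients are masked to ±0.5 s around
high-prominence excursions, and both signals are amplitude-compressed
(signed square root) before correlating, so that a single large area
excursion (the ramp collapse edge, or respiratory reopening near collapse)
cannot outweigh the joint alignment of the two sync compressions. Captures
with fewer than two detectable transients in either channel are rejected
as unsyncable.

## Collapse force and its uncertainty

CF is defined by the **first crossing** of the occlusion threshold during
the ascending ramp (a minimum force; ties break toward earlier time), with
explicit errors for series that never occlude or are occluded before the
ramp starts.

The uncertainty interval reflects that the underlying pressure is a
waveform: near collapse, the area oscillates with the cardiac and
respiratory cycles, so a range of forces could have been the first to
occlude. The measured first crossing is trough-aligned and is therefore
itself the lower envelope's crossing (`cf_lo = cf`). The upper bound is
the force from which occlusion is *sustained* — just past the last
reopening above the threshold on the ascending ramp, which is where the
waveform's upper envelope crosses the threshold, resolved per sample. If
the ramp ends while peaks still reopen the vein, the crossing is linearly
extrapolated from the trend of per-cycle area maxima over a 4 s
near-collapse window and clipped to the observed force range with a
warning. Extrapolation is done in force coordinates (the ramp makes force
and time interchangeable; force is the natural axis for a force bound).
With all variation disabled the two bounds coincide with the estimate
exactly, and the interval widens with respiratory amplitude, which is the
behaviour the uncertainty is meant to encode.

## Calibration conventions

All fits are ordinary least squares with intercept (`stats::lm`), the
dependent variable being average invasive CVP. Three conventions are load
bearing and were verified against the bundled table:

* the hydrostatic offset enters every fit and the trained model in mmHg
  (multiplied by C = 0.7356), not cmH₂O;
* the SD of the error uses the sample (n−1) denominator about the signed
  error mean;
* JVP agreement is computed on the raw JVP readings in mmHg against
  invasive CVP (the identity-line comparison), not through a refitted
  regression.

The trained model CVP = 0.42·CF + 0.054 + HO(mmHg) is applied as a fixed
formula; because its published coefficients are rounded, recomputed
predictions can differ from externally printed values by a few hundredths
of a mmHg — and for two subjects in the bundled table by more, an
inconsistency in the printed source itself that the tests surface rather
than hide.

## Uncertainty intervals and overlap accuracy

Per-method intervals: CF-based methods map the collapse-force interval
through the calibrated regression (the interval lives in predicted-CVP
units); methods that include the hydrostatic offset add its fixed
±0.5 mmHg; JVP carries its fixed ±0.5 mmHg repeatability/rounding
uncertainty. Overlap accuracy is a point-in-interval test against the
scalar invasive CVP — deliberately ignoring the invasive measurement's own
(respiratory) uncertainty so the statistic measures the noninvasive
method's interval alone. Subjects measured on the external jugular vein
are excluded from CF-based denominators; JVP attempts that failed for
positioning reasons count as forced misses, and JVP never attempted is
excluded.

## Waveform inverse model

During the hold phase the probe force is constant, so frame-to-frame area
changes encode pressure changes. For each frame the venous pressure is the
value whose forward-model area matches the segmented area. Two routes
exist: the generic `invert_frame()` bisects the monotone forward model on
a [−5, 40] mmHg bracket to an area tolerance of \(10^{-3} A_{\mathrm{ref}}\)
(the quantified meaning of "areas about equal"), and works for any
monotone forward backend; `estimate_cvp_waveform()` exploits the built-in
law's explicit transmural inverse, \(P = P_{ext} + k\,(\alpha^{n_+} -
\alpha^{-n_-})\), which is algebraically identical and vectorizes over
the ~1400 hold frames.

The absolute level is anchored to the CF-based mean CVP estimate (the
CF-only prediction, matching the chain that produced the anchor): the
stiffness \(k\) is calibrated so the reconstructed waveform's time mean
equals the anchor within 0.1 mmHg. Because the reconstruction is linear in
\(k\), this one-dimensional physical-parameter calibration has a closed
form; an additive shift would instead leave the forward model inconsistent
with the waveform it produced. Frames whose required pressure falls
outside the bracket are flagged and linearly interpolated, and more than
20 % of them aborts the solve with a diagnostic. The carotid pressure
input is the simplified two-level (end-diastole / peak-systole) pulse,
taken from configuration rather than estimated from the images; its
systolic window overlaps the v wave, which is how the model raises the
reconstructed v peak relative to the a/c peak even when the *area*
waveform shows the opposite ordering.

## Numerical choices and degenerate inputs

* Tube-law inversion: vectorized bisection, 80 iterations on a bracketed
  monotone function (resolution ~\(2^{-80}\) of the bracket); no
  convergence failures are possible for valid parameters.
* The envelope chunk length (0.5 s) is a compromise: at least half a
  cardiac period at typical heart rates, short enough to give several
  points over the near-collapse window.
* Zero-variance degenerate inputs are first-class: constant waveforms give
  zero respiratory SD and zero-width intervals; zero-variation captures
  give zero-width collapse intervals; constant-area holds reconstruct a
  constant waveform at the anchor.
* Mean-anchoring fails loudly (rather than silently flipping sign) when
  the anchor is inconsistent with the hold-phase external pressure.

## Problem sizes in the test-suite

The packaged tests and the acceptance script run on an 11-subject cohort
(matching the bundled study's size), 100 seeded captures for collapse-force
detection and 100 seeded lags for synchronization, 300 random operating
points for the frame-inversion round trip, and single ~49 s captures at
100 Hz for the waveform reconstruction checks. These sizes keep the whole
suite under a minute on one CPU while giving the stochastic checks
two-digit resolution.

## Known limitations

* The reduced-order tube law has no bending stiffness, contact mechanics,
  or tissue shear; absolute parameter values are nominal, and only the
  *structure* of the inverse problem transfers to a finite-element backend.
* The collapse-force interval is one-sided above the estimate by
  construction (the first crossing is already the trough-aligned minimum
  feasible force); a deeper model of segmentation noise would be needed to
  justify widening below it.
* Carotid pressure is an input, not an estimate; reconstructed waveform
  morphology inherits any mismatch in its assumed levels and timing.
* The calibration is a population fit over 11 subjects; its uncertainties
  are those of a pilot-scale cohort and the package makes no attempt at
  per-patient recalibration.
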