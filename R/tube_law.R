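#' Vessel and probe-coupling parameters
#'
#' Reduced-order description of the compressed internal jugular vein (IJV),
#' its carotid neighbour, and the force-to-pressure coupling of the probe.
#' The IJV follows a classic collapsible-tube law relating the normalized
#' lumen area `alpha = A / a_ref` to transmural pressure (internal minus
#' external):
#'
#' `P_tm(alpha) = k_stiff * (alpha^n_pos - alpha^(-n_neg))`
#'
#' which is strictly increasing in `alpha`, passes through zero at the
#' unstressed area `a_ref`, stiffens rapidly in distension (large `n_pos`),
#' and collapses smoothly (`alpha -> 0`) as transmural pressure becomes
#' strongly negative. The probe applies a uniform surface pressure
#' `transmission * force / contact_area`, of which the `transmission`
#' fraction reaches the vessel through the intervening tissue; the pulsating
#' carotid adds `kappa * (carotid pressure - diastolic reference)` to the
#' IJV's external pressure. The carotid itself, far stiffer than the vein,
#' is modeled with a linear compliance about its reference area.
#'
#' Defaults are chosen to represent a mid-sized adult IJV imaged with a
#' large-footprint probe; none of them are fitted to patient data.
#'
#' @param a_ref Unstressed IJV lumen area, mm^2.
#' @param k_stiff Tube-law stiffness scale, mmHg.
#' @param n_pos,n_neg Tube-law exponents (distension / collapse branches).
#' @param contact_area_cm2 Probe footprint, cm^2.
#' @param transmission Fraction of the probe surface pressure reaching the
#'   vessel, in (0, 1].
#' @param kappa Fraction of the carotid pulse pressure added to the IJV's
#'   external pressure (carotid-IJV proximity coupling).
#' @param carotid_a_ref Carotid reference area, mm^2.
#' @param carotid_compliance Carotid linear compliance, mm^2 per mmHg.
#' @param carotid_p_ref Carotid reference (diastolic) pressure, mmHg.
#' @return A `vessel_params` list.
#' @export
vessel_params <- function(a_ref = 120, k_stiff = 0.3, n_pos = 10,
                          n_neg = 0.35, contact_area_cm2 = 15,
                          transmission = 0.21, kappa = 0.02,
                          carotid_a_ref = 40, carotid_compliance = 0.15,
                          carotid_p_ref = 80) {
  stopifnot(a_ref > 0, k_stiff > 0, n_pos > 0, n_neg > 0,
            contact_area_cm2 > 0, transmission > 0, transmission <= 1,
            kappa >= 0, carotid_a_ref > 0, carotid_compliance >= 0)
  structure(list(a_ref = a_ref, k_stiff = k_stiff, n_pos = n_pos,
                 n_neg = n_neg, contact_area_cm2 = contact_area_cm2,
                 transmission = transmission, kappa = kappa,
                 carotid_a_ref = carotid_a_ref,
                 carotid_compliance = carotid_compliance,
                 carotid_p_ref = carotid_p_ref),
            class = "vessel_params")
}

# 1 N / cm^2 = 10 kPa = 75.0062 mmHg
MMHG_PER_N_CM2 <- 75.0062

#' Probe surface force converted to vessel-level external pressure
#'
#' @param force_n Probe force, N.
#' @param vessel A [vessel_params].
#' @return External pressure contribution at the vessel, mmHg.
#' @export
probe_pressure <- function(force_n, vessel) {
  vessel$transmission * force_n / vessel$contact_area_cm2 * MMHG_PER_N_CM2
}

# Transmural pressure at normalized area alpha (vectorized).
tube_transmural <- function(alpha, vessel) {
  vessel$k_stiff * (alpha^vessel$n_pos - alpha^(-vessel$n_neg))
}

# Invert the tube law: normalized area alpha at transmural pressure p_tm.
# Vectorized bisection; the law is strictly monotone so convergence is
# guaranteed to ~2^-80 of the bracket.
tube_alpha <- function(p_tm, vessel, iters = 80) {
  lo <- rep(1e-12, length(p_tm))
  hi <- rep(pmax(2, (pmax(p_tm, 0) / vessel$k_stiff + 1)^(1 / vessel$n_pos)
                 + 1), length.out = length(p_tm))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    up <- tube_transmural(mid, vessel) < p_tm
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Forward model: vessel areas under pressure and probe force
#'
#' External pressure on the IJV is the probe-transmitted surface pressure
#' plus the carotid coupling term `kappa * (p_carotid - carotid_p_ref)`; the
#' IJV area then solves the monotone tube law at the resulting transmural
#' pressure, and the carotid area follows its linear compliance. All inputs
#' are vectorized over frames.
#'
#' @param p_ijv Venous internal pressure, mmHg.
#' @param p_carotid Carotid internal pressure, mmHg.
#' @param probe_force Probe force, N (`>= 0`).
#' @param vessel A [vessel_params].
#' @return List with `ijv_area` and `carotid_area` (mm^2).
#' @export
forward_areas <- function(p_ijv, p_carotid, probe_force, vessel) {
  if (any(probe_force < 0)) stop("probe_force must be >= 0")
  p_ext <- probe_pressure(probe_force, vessel) +
    vessel$kappa * (p_carotid - vessel$carotid_p_ref)
  alpha <- tube_alpha(p_ijv - p_ext, vessel)
  carotid <- pmax(0, vessel$carotid_a_ref +
                    vessel$carotid_compliance * (p_carotid - vessel$carotid_p_ref))
  list(ijv_area = vessel$a_ref * alpha, carotid_area = carotid)
}

#' Invert a single frame: venous pressure from a measured IJV area
#'
#' Finds the internal pressure `p_ijv` whose forward-model IJV area matches
#' the measured area within `tol_mm2`, by bisection over `bracket`; the
#' forward model is monotone in `p_ijv` so the root is unique when it exists.
#' A measured area outside the range attainable over the bracket is flagged
#' unconverged rather than extrapolated.
#'
#' @param measured_area Segmented IJV area for the frame, mm^2.
#' @param p_carotid Carotid pressure for the frame, mmHg.
#' @param probe_force Probe force for the frame, N.
#' @param vessel A [vessel_params].
#' @param bracket Search interval for `p_ijv`, mmHg.
#' @param tol_mm2 Area-matching tolerance; default `1e-3 * a_ref`.
#' @return List with `p_ijv` (mmHg, `NA` if unconverged), `converged`
#'   (logical), and `residual_mm2`.
#' @export
invert_frame <- function(measured_area, p_carotid, probe_force, vessel,
                         bracket = c(-5, 40), tol_mm2 = NULL) {
  if (is.null(tol_mm2)) tol_mm2 <- 1e-3 * vessel$a_ref
  area_at <- function(p) forward_areas(p, p_carotid, probe_force,
                                       vessel)$ijv_area
  lo <- bracket[1]; hi <- bracket[2]
  a_lo <- area_at(lo); a_hi <- area_at(hi)
  if (measured_area < a_lo - tol_mm2 || measured_area > a_hi + tol_mm2)
    return(list(p_ijv = NA_real_, converged = FALSE,
                residual_mm2 = min(abs(measured_area - a_lo),
                                   abs(measured_area - a_hi))))
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    a_mid <- area_at(mid)
    if (abs(a_mid - measured_area) <= tol_mm2)
      return(list(p_ijv = mid, converged = TRUE,
                  residual_mm2 = abs(a_mid - measured_area)))
    if (a_mid < measured_area) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  list(p_ijv = mid, converged = abs(area_at(mid) - measured_area) <= tol_mm2,
       residual_mm2 = abs(area_at(mid) - measured_area))
}
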