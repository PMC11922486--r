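#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis chain with defaults set
#' to the values the method is defined with: the 0.5 mm^2 occlusion
#' threshold, the 1 Hz cardiac/respiratory boundary, the 0.5 mmHg
#' hydrostatic and JVP uncertainties, the 10 cm hydrostatic distance, the
#' 0.7356 cmH2O-to-mmHg constant, the near-collapse envelope window, the
#' inverse-solve pressure bracket, and the vessel model parameters.
#'
#' @param ... Overrides for any top-level config field.
#' @return A `qcu_config` list.
#' @export
qcu_config <- function(...) {
  cfg <- list(
    cutoff_hz = 1.0,
    occlusion_mm2 = OCCLUSION_THRESHOLD_MM2,
    cf_window_s = 3,
    ho_uncertainty_mmhg = HO_UNCERTAINTY_MMHG,
    jvp_uncertainty_mmhg = JVP_UNCERTAINTY_MMHG,
    ho_distance_cm = HO_DISTANCE_CM,
    cmh2o_to_mmhg = C_MMHG_PER_CMH2O,
    inverse_bracket_mmhg = c(-5, 40),
    vessel = unclass(vessel_params()),
    protocol = unclass(capture_protocol())
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0 || is.null(names(over)) || any(names(over) == ""))
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
  }
  stopifnot(cfg$cutoff_hz > 0, cfg$occlusion_mm2 > 0, cfg$cf_window_s > 0,
            cfg$ho_uncertainty_mmhg > 0, cfg$jvp_uncertainty_mmhg > 0)
  structure(cfg, class = "qcu_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_qcu_config` returns a `qcu_config`; `write_qcu_config`
#'   returns `path` invisibly.
#' @export
read_qcu_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(qcu_config, raw)
}

#' @rdname read_qcu_config
#' @param config A `qcu_config`.
#' @export
write_qcu_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Serialize a capture to a directory
#'
#' Channels are written as `(t, value)` CSV files (`force.csv`,
#' `ijv_area.csv`, `carotid_area.csv`, plus `true_cvp.csv` and
#' `true_carotid_pressure.csv` for synthetic captures) with a JSON sidecar
#' `capture.json` holding the per-sample phase labels, sample rate,
#' protocol, vessel parameters, and scalar truth fields.
#'
#' @param capture A `qcu_capture`.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_capture <- function(capture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name)
    utils::write.csv(as.data.frame(x), file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(capture$force, "force")
  wr(capture$ijv_area, "ijv_area")
  wr(capture$carotid_area, "carotid_area")
  meta <- list(sample_rate = capture$sample_rate, phase = capture$phase,
               protocol = unclass(capture$protocol),
               vessel = unclass(capture$vessel),
               units = list(force = capture$force$units,
                            ijv_area = capture$ijv_area$units,
                            carotid_area = capture$carotid_area$units))
  if (!is.null(capture$truth)) {
    wr(capture$truth$cvp, "true_cvp")
    wr(capture$truth$carotid_pressure, "true_carotid_pressure")
    meta$truth <- capture$truth[c("cf", "collapse_time", "mean_cvp",
                                  "theta_deg", "lag_s")]
  }
  jsonlite::write_json(meta, file.path(dir, "capture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a capture written by [write_capture()]
#'
#' @param dir Capture directory.
#' @return A `qcu_capture`.
#' @export
read_capture <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "capture.json"))
  fs <- meta$sample_rate
  rd <- function(name, units) {
    df <- utils::read.csv(file.path(dir, paste0(name, ".csv")))
    qcu_ts(df$value, fs, t0 = df$t[1], units = units)
  }
  cap <- list(force = rd("force", meta$units$force),
              ijv_area = rd("ijv_area", meta$units$ijv_area),
              carotid_area = rd("carotid_area", meta$units$carotid_area),
              phase = meta$phase,
              sample_rate = fs,
              protocol = do.call(capture_protocol, meta$protocol),
              vessel = do.call(vessel_params, meta$vessel))
  if (!is.null(meta$truth)) {
    cap$truth <- as.list(meta$truth)
    cap$truth$cvp <- rd("true_cvp", "mmHg")
    cap$truth$carotid_pressure <- rd("true_carotid_pressure", "mmHg")
  }
  structure(cap, class = "qcu_capture")
}

#' Simulate a cohort and write it to disk
#'
#' Orchestration front-end for [synth_cohort()]: writes the study table
#' (`study_table.csv`) and one capture directory per subject
#' (`capture_01`, ...) under `out_dir`. Deterministic for a given seed.
#'
#' @param out_dir Output directory.
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param config A [qcu_config()].
#' @return The cohort list, invisibly.
#' @export
qcu_simulate <- function(out_dir, n_subjects = 11, seed = 1,
                         config = qcu_config()) {
  cohort <- synth_cohort(n_subjects,
                         vessel = do.call(vessel_params, config$vessel),
                         protocol = do.call(capture_protocol, config$protocol),
                         seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_study_table(cohort$table, file.path(out_dir, "study_table.csv"))
  for (i in seq_along(cohort$captures))
    write_capture(cohort$captures[[i]],
                  file.path(out_dir, sprintf("capture_%02d", i)))
  invisible(cohort)
}

#' Calibrate a study table and write a fit report
#'
#' Runs [fit_linear()] and returns (and optionally writes as JSON) the fit
#' report: coefficients, per-coefficient p-values, r-squared, MAE, and the
#' SD of the error.
#'
#' @param table A [study_table] or a path readable by [load_study_table()].
#' @param predictors Passed to [fit_linear()].
#' @param out Optional JSON report path.
#' @return The `regression_fit`, invisibly if `out` is given.
#' @export
qcu_calibrate <- function(table, predictors = "CF", out = NULL) {
  if (is.character(table)) table <- load_study_table(table)
  fit <- fit_linear(table, predictors)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(predictors = fit$predictor_names,
           coefficients = as.list(fit$coefficients),
           p_values = as.list(fit$p_values),
           r_squared = fit$r_squared, mae = fit$mae,
           sd_error = fit$sd_error, n = fit$n),
      out, auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  fit
}

#' Overlap-accuracy evaluation across all four methods
#'
#' Builds per-subject uncertainty intervals for the CF, CF+HO, JVP, and
#' trained-model estimates and computes each method's overlap accuracy
#' against average invasive CVP. CF-based methods need per-subject collapse
#' estimates with uncertainty bounds; methods whose inputs are unavailable
#' are skipped.
#'
#' @param table A [study_table].
#' @param collapses Optional named list of `collapse_estimate`s keyed by
#'   subject id (as character); required for the CF-based methods.
#' @param out Optional JSON path for the report set.
#' @return Named list of `overlap_report`s.
#' @export
qcu_evaluate <- function(table, collapses = NULL, out = NULL) {
  if (is.character(table)) table <- load_study_table(table)
  reports <- list()
  if (any(table$jvp_status == "measured")) {
    ids <- as.character(table$subject_id)
    ivs <- stats::setNames(lapply(seq_len(nrow(table)), function(i) {
      if (table$jvp_status[i] != "measured") return(NULL)
      method_interval("JVP", table[i, ])
    }), ids)
    reports$JVP <- overlap_accuracy("JVP", table, ivs)
  }
  if (!is.null(collapses)) {
    fits <- list(CF = fit_linear(table, "CF"),
                 CF_HO = fit_linear(table, c("CF", "HO")))
    for (method in c("CF", "CF_HO", "TrainedModel")) {
      ids <- as.character(table$subject_id)
      ivs <- stats::setNames(lapply(seq_len(nrow(table)), function(i) {
        id <- ids[i]
        if (is.null(collapses[[id]])) return(NULL)
        method_interval(method, table[i, ], collapse = collapses[[id]],
                        fit = fits[[method]])
      }), ids)
      reports[[method]] <- overlap_accuracy(method, table, ivs)
    }
  }
  if (length(reports) == 0) stop("nothing to evaluate: empty table")
  if (!is.null(out)) {
    jsonlite::write_json(lapply(reports, unclass), out, auto_unbox = TRUE,
                         digits = NA)
    return(invisible(reports))
  }
  reports
}

#' Run the waveform inverse solve on a capture directory or object
#'
#' @param capture A `qcu_capture` or a directory written by
#'   [write_capture()].
#' @param anchor_cvp Scalar mean CVP anchor in mmHg (the CF-based estimate).
#' @param config A [qcu_config()].
#' @param out Optional output directory for `cvp_waveform.csv` and
#'   `inverse_meta.json`.
#' @return An `inverse_result`.
#' @export
qcu_invert <- function(capture, anchor_cvp, config = qcu_config(),
                       out = NULL) {
  if (is.character(capture)) capture <- read_capture(capture)
  res <- estimate_cvp_waveform(capture, anchor_cvp = anchor_cvp,
                               bracket = config$inverse_bracket_mmhg)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(res$cvp_waveform),
                     file.path(out, "cvp_waveform.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(anchor_mean = res$anchor_mean,
           converged_frames = res$converged_frames,
           n_frames = length(res$cvp_waveform$values),
           k_stiff_calibrated = res$k_stiff_calibrated,
           max_residual_mm2 = max(res$per_frame_residual[res$converged])),
      file.path(out, "inverse_meta.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
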