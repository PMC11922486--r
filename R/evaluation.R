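#' Fixed measurement uncertainties
#'
#' `HO_UNCERTAINTY_MMHG`: hydrostatic-pressure uncertainty (angle imprecision
#' and population variation in the atrium-to-measurement-site distance),
#' applied after conversion to pressure units. `JVP_UNCERTAINTY_MMHG`:
#' bedside JVP repeatability and whole-number rounding, applied in each
#' direction.
#' @name uncertainty_constants
NULL

#' @rdname uncertainty_constants
#' @export
HO_UNCERTAINTY_MMHG <- 0.5

#' @rdname uncertainty_constants
#' @export
JVP_UNCERTAINTY_MMHG <- 0.5

new_interval <- function(center, lo, hi, source) {
  if (!(lo <= center && center <= hi))
    stop("invalid interval: need lo <= center <= hi")
  structure(list(center = center, lo = lo, hi = hi, source = source),
            class = "uncertainty_interval")
}

#' @export
print.uncertainty_interval <- function(x, ...) {
  cat(sprintf("[%.2f, %.2f] mmHg (center %.2f, source %s)\n",
              x$lo, x$hi, x$center, x$source))
  invisible(x)
}

#' Uncertainty interval of a noninvasive CVP estimate
#'
#' Builds the per-subject uncertainty interval for one estimation method:
#' \describe{
#'   \item{CF}{center is the calibrated prediction at the measured collapse
#'     force; the bounds map the collapse-force uncertainty interval
#'     (`cf_lo`, `cf_hi`) through the same regression.}
#'   \item{CF_HO}{as CF but through the CF+HO fit, widened by the
#'     hydrostatic-pressure uncertainty (0.5 mmHg each side).}
#'   \item{JVP}{the measured JVP with the fixed measurement uncertainty
#'     (0.5 mmHg each side).}
#'   \item{TrainedModel}{collapse-force bounds mapped through the fixed
#'     trained model, widened by the hydrostatic uncertainty.}
#' }
#'
#' @param method One of `"CF"`, `"CF_HO"`, `"JVP"`, `"TrainedModel"`.
#' @param record One row of a [study_table].
#' @param collapse A `collapse_estimate` with bounds filled (CF-based
#'   methods).
#' @param fit A `regression_fit` (methods CF and CF_HO).
#' @return An `uncertainty_interval`.
#' @export
method_interval <- function(method = c("CF", "CF_HO", "JVP", "TrainedModel"),
                            record, collapse = NULL, fit = NULL) {
  method <- match.arg(method)
  if (method == "JVP") {
    if (is.na(record$jvp_mmhg)) stop("record has no measured JVP")
    return(new_interval(record$jvp_mmhg,
                        record$jvp_mmhg - JVP_UNCERTAINTY_MMHG,
                        record$jvp_mmhg + JVP_UNCERTAINTY_MMHG,
                        "jvp_measurement"))
  }
  if (is.null(collapse) || is.na(collapse$cf_lo))
    stop("CF-based methods need a collapse estimate with bounds filled")
  at_cf <- function(cf) {
    r <- record
    r$cf_n <- cf
    if (method == "TrainedModel") apply_trained_model(r)
    else stats::predict(fit, r)
  }
  if (method != "TrainedModel" && is.null(fit))
    stop("methods CF and CF_HO need a regression fit")
  center <- at_cf(collapse$cf)
  bounds <- range(at_cf(collapse$cf_lo), at_cf(collapse$cf_hi), center)
  pad <- if (method %in% c("CF_HO", "TrainedModel")) HO_UNCERTAINTY_MMHG else 0
  new_interval(center, bounds[1] - pad, bounds[2] + pad,
               switch(method, CF = "cf_waveform", CF_HO = "combined",
                      TrainedModel = "combined"))
}

#' Uncertainty interval of the invasive CVP measurement
#'
#' The invasive waveform's cardiac-cycle content is filtered out and the
#' interval is taken as the mean plus/minus two standard deviations of the
#' respiratory component.
#'
#' @param waveform Invasive CVP waveform, a [qcu_ts] of at least 10 s.
#' @return An `uncertainty_interval` with source `"invasive_respiratory"`.
#' @export
invasive_interval <- function(waveform) {
  stopifnot(inherits(waveform, "qcu_ts"))
  if (length(waveform$values) / waveform$sample_rate < 10)
    stop("waveform too short: need at least 10 s")
  m <- mean(waveform$values)
  s <- respiratory_sd(waveform)
  new_interval(m, m - 2 * s, m + 2 * s, "invasive_respiratory")
}

#' Uncertainty-overlap accuracy of a method against invasive CVP
#'
#' A subject scores a hit when their uncertainty interval contains the
#' scalar average invasive CVP (point-in-interval; the invasive
#' measurement's own uncertainty is deliberately not used). Eligibility
#' follows the method: CF-based methods exclude subjects measured on the
#' external jugular vein (a thrombosed IJV); the JVP method counts subjects
#' whose JVP was attempted but unmeasurable as forced misses and excludes
#' subjects where JVP was not attempted. Accuracy is
#' `n_hits / (n_eligible + n_forced_misses)`.
#'
#' @param method One of `"CF"`, `"CF_HO"`, `"JVP"`, `"TrainedModel"`.
#' @param table A [study_table].
#' @param intervals Named list of `uncertainty_interval`s keyed by
#'   `subject_id` (as character), covering every eligible subject.
#' @return An `overlap_report`: `method`, `n_eligible`, `n_hits`,
#'   `n_forced_misses`, `accuracy`.
#' @export
overlap_accuracy <- function(method = c("CF", "CF_HO", "JVP", "TrainedModel"),
                             table, intervals) {
  method <- match.arg(method)
  validate_study_table(table)
  if (method == "JVP") {
    eligible <- table$jvp_status == "measured"
    forced <- sum(table$jvp_status == "attempted_unmeasurable")
  } else {
    eligible <- !(table$vein %in% c("LEJ", "REJ")) & !is.na(table$cf_n)
    forced <- 0L
  }
  if (!any(eligible)) stop("no eligible subjects for method ", method)
  ids <- as.character(table$subject_id[eligible])
  missing <- setdiff(ids, names(intervals))
  if (length(missing) > 0)
    stop("missing interval(s) for subject(s): ",
         paste(missing, collapse = ", "))
  cvp <- table$avg_invasive_cvp_mmhg[eligible]
  hits <- vapply(seq_along(ids), function(i) {
    iv <- intervals[[ids[i]]]
    iv$lo <= cvp[i] && cvp[i] <= iv$hi
  }, logical(1))
  structure(list(method = method, n_eligible = sum(eligible),
                 n_hits = sum(hits), n_forced_misses = forced,
                 accuracy = sum(hits) / (sum(eligible) + forced)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d hits (%d forced miss%s) -> accuracy %.3f\n",
              x$method, x$n_hits, x$n_eligible + x$n_forced_misses,
              x$n_forced_misses, if (x$n_forced_misses == 1) "" else "es",
              x$accuracy))
  invisible(x)
}

#' Bar chart of overlap accuracies
#'
#' Small summary figure of per-method uncertainty-overlap accuracy.
#'
#' @param reports List of `overlap_report`s.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_overlap_accuracy <- function(reports, ...) {
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  names(acc) <- vapply(reports, function(r) r$method, character(1))
  graphics::barplot(acc, ylim = c(0, 1), ylab = "Overlap accuracy", ...)
}
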