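#' Physical constants of the calibration chain
#'
#' `C_MMHG_PER_CMH2O` (0.7356) converts cmH2O to mmHg. `HO_DISTANCE_CM` (10)
#' is the assumed fixed distance in cm from the middle of the right atrium to
#' the jugular measurement site, used by the hydrostatic-offset model.
#'
#' @name constants
NULL

#' @rdname constants
#' @export
C_MMHG_PER_CMH2O <- 0.7356

#' @rdname constants
#' @export
HO_DISTANCE_CM <- 10

#' Hydrostatic offset from the inclination angle
#'
#' HO = 10 sin(theta) cmH2O: the vertical blood column between the
#' mid-right-atrium and the jugular measurement site, assuming a fixed 10 cm
#' along-body distance between the two.
#'
#' @param theta_deg Inclination angle of the vein above the right atrium, in
#'   degrees, within `[0, 90]`.
#' @return Hydrostatic offset in cmH2O.
#' @examples
#' hydrostatic_offset(30)  # 5
#' @export
hydrostatic_offset <- function(theta_deg) {
  if (any(theta_deg < 0 | theta_deg > 90))
    stop("theta_deg must be within [0, 90]")
  HO_DISTANCE_CM * sin(theta_deg * pi / 180)
}

#' Convert cmH2O to mmHg
#'
#' @param p Pressure in cmH2O.
#' @return Pressure in mmHg (`p * 0.7356`).
#' @export
cmh2o_to_mmhg <- function(p) p * C_MMHG_PER_CMH2O

#' Convert a jugular pulsation height reading to pressure
#'
#' A bedside JVP reading is the distance `h` (cm, along the inclined body
#' axis) from the sternal angle reference to the top of the visible jugular
#' pulsations; `h * sin(theta)` is the vertical height and multiplying by the
#' cmH2O-to-mmHg constant yields pressure: `JVP = h * sin(theta) * 0.7356`.
#'
#' @param h_cm Pulsation height along the body axis, cm, `>= 0`.
#' @param theta_deg Inclination angle in degrees, `[0, 90]`.
#' @return JVP in mmHg.
#' @examples
#' jvp_to_mmhg(10, 30)  # 3.678
#' @export
jvp_to_mmhg <- function(h_cm, theta_deg) {
  if (any(h_cm < 0)) stop("pulsation height must be >= 0")
  h_cm * sin(theta_deg * pi / 180) * C_MMHG_PER_CMH2O
}

#' Ordinary least squares calibration against invasive CVP
#'
#' Regresses average invasive CVP on the chosen predictors (with intercept)
#' over the complete records of a study table. The hydrostatic offset enters
#' the design matrix in mmHg (converted by 0.7356); JVP-based fits use only
#' subjects with a measured JVP.
#'
#' @param table A [study_table].
#' @param predictors Character subset of `c("CF", "HO", "JVP")`: collapse
#'   force (N), hydrostatic offset (supplied to the fit in mmHg), and
#'   measured JVP (mmHg).
#' @return A `regression_fit` list: `predictor_names`, `coefficients` (named,
#'   intercept first), `p_values` (two-sided t-tests per coefficient),
#'   `r_squared`, `mae` (mean absolute residual, mmHg), `sd_error` (sample SD
#'   of residuals, n-1 denominator), `residuals`, `n`, and the underlying
#'   `lm` object.
#' @examples
#' fit <- fit_linear(qcu_study_table(), "CF")
#' round(fit$coefficients, 3)   # intercept -0.053, slope 1.047
#' round(fit$r_squared, 2)      # 0.82
#' @export
fit_linear <- function(table, predictors = "CF") {
  validate_study_table(table)
  predictors <- match.arg(predictors, c("CF", "HO", "JVP"), several.ok = TRUE)
  cols <- list(CF = table$cf_n,
               HO = cmh2o_to_mmhg(table$ho_cmh2o),
               JVP = table$jvp_mmhg)
  X <- do.call(cbind, cols[predictors])
  colnames(X) <- predictors
  y <- table$avg_invasive_cvp_mmhg
  complete <- stats::complete.cases(X, y)
  X <- X[complete, , drop = FALSE]
  y <- y[complete]
  if (length(y) < length(predictors) + 2)
    stop("insufficient complete records for ", length(predictors),
         " predictor(s): have ", length(y))
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("singular design matrix")
  df <- data.frame(y = y, X)
  model <- stats::lm(y ~ ., data = df)
  smry <- summary(model)
  res <- stats::residuals(model)
  structure(list(
    predictor_names = predictors,
    coefficients = stats::coef(model),
    p_values = smry$coefficients[, "Pr(>|t|)"],
    r_squared = smry$r.squared,
    mae = mean(abs(res)),
    sd_error = stats::sd(res),
    residuals = as.numeric(res),
    n = length(y),
    model = model
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("OLS calibration of invasive CVP on",
      paste(x$predictor_names, collapse = " + "), sprintf("(n = %d)\n", x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("r^2 = %.3f  MAE = %.3f mmHg  SD(err) = %.3f mmHg\n",
              x$r_squared, x$mae, x$sd_error))
  cat("p-values:", paste(sprintf("%s %.2g", names(x$p_values), x$p_values),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Predict CVP for study records from a calibration fit
#'
#' Linear evaluation of the fitted coefficients on each record's predictor
#' values (HO converted to mmHg).
#'
#' @param object A `regression_fit` from [fit_linear()].
#' @param newdata A [study_table] (or subset of rows).
#' @param ... Unused.
#' @return Predicted CVP in mmHg, one value per row.
#' @export
predict.regression_fit <- function(object, newdata, ...) {
  cols <- list(CF = newdata$cf_n,
               HO = cmh2o_to_mmhg(newdata$ho_cmh2o),
               JVP = newdata$jvp_mmhg)
  X <- do.call(cbind, cols[object$predictor_names])
  if (any(!stats::complete.cases(X)))
    stop("record is missing a fit predictor")
  drop(cbind(1, X) %*% object$coefficients)
}

#' Apply the previously trained CVP model
#'
#' Fixed linear model carried over from an earlier healthy-volunteer training
#' study, applied without refitting:
#' `CVP = 0.42 * CF + 0.054 + HO_mmHg`, with the hydrostatic offset converted
#' from cmH2O to mmHg. Because the published coefficients are rounded, values
#' recomputed here can differ from an externally printed prediction by a few
#' hundredths of a mmHg.
#'
#' @param table A [study_table] (or rows thereof) with `cf_n` and `ho_cmh2o`.
#' @return Predicted CVP in mmHg per row.
#' @examples
#' apply_trained_model(qcu_study_table()[6, ])  # 0.9906
#' @export
apply_trained_model <- function(table) {
  if (any(is.na(table$cf_n)) || any(is.na(table$ho_cmh2o)))
    stop("record is missing CF or HO")
  0.42 * table$cf_n + 0.054 + cmh2o_to_mmhg(table$ho_cmh2o)
}

#' Agreement metrics between predicted and reference CVP
#'
#' @param pred,truth Numeric vectors of equal length `>= 2`, mmHg.
#' @return List with `r_squared` (squared Pearson correlation), `mae`
#'   (mean absolute difference), and `sd_error` (sample SD, n-1 denominator,
#'   of the signed differences about their mean).
#' @examples
#' tab <- qcu_study_table()
#' m <- agreement_metrics(tab$trained_model_cvp_mmhg, tab$avg_invasive_cvp_mmhg)
#' round(c(m$r_squared, m$mae, m$sd_error), 2)  # 0.46 1.60 2.17
#' @export
agreement_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 paired values")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    stop("zero variance in predictions or reference values")
  err <- pred - truth
  list(r_squared = stats::cor(pred, truth)^2,
       mae = mean(abs(err)),
       sd_error = stats::sd(err))
}
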