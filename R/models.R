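#' Construct a linear VO2 prediction model
#'
#' A VO2 prediction equation of the form
#' `VO2 = intercept + coef_mad * MAD + coef_dmad * |dMAD|
#'        + coef_expfs * exp(f_s)` (mL/kg/min),
#' where MAD and |dMAD| are in mg and `f_s` in Hz. Fixed-epoch models carry
#' only the MAD term; floating-epoch models carry all three.
#'
#' @param intercept Intercept in mL/kg/min.
#' @param coef_mad Coefficient on mean MAD, (mL/kg/min)/mg.
#' @param coef_dmad Coefficient on mean |dMAD|, (mL/kg/min)/mg, or `NULL`.
#' @param coef_expfs Coefficient on `exp(mean f_s)`, mL/kg/min per unit, or
#'   `NULL`.
#' @param name Model name.
#' @param epoch_kind `"fixed6s"` or `"floating"`.
#' @param training_label Free-form provenance label.
#' @param p_values Optional named numeric vector of per-coefficient
#'   p-values.
#' @return An object of class `vo2_model`.
#' @export
vo2_model <- function(intercept, coef_mad, coef_dmad = NULL,
                      coef_expfs = NULL, name = "custom",
                      epoch_kind = c("fixed6s", "floating"),
                      training_label = "", p_values = NULL) {
  epoch_kind <- match.arg(epoch_kind)
  if (epoch_kind == "floating" && (is.null(coef_dmad) || is.null(coef_expfs)))
    stop("floating-epoch models require coef_dmad and coef_expfs")
  structure(list(name = name, epoch_kind = epoch_kind,
                 intercept = as.numeric(intercept),
                 coef_mad = as.numeric(coef_mad),
                 coef_dmad = if (!is.null(coef_dmad)) as.numeric(coef_dmad),
                 coef_expfs = if (!is.null(coef_expfs)) as.numeric(coef_expfs),
                 training_label = training_label,
                 p_values = p_values),
            class = "vo2_model")
}

#' @export
print.vo2_model <- function(x, ...) {
  cat(sprintf("<vo2_model> %s (%s epochs)%s\n", x$name, x$epoch_kind,
              if (nzchar(x$training_label))
                paste0(" [", x$training_label, "]") else ""))
  cat(sprintf("  VO2 = %.4g + %.4g*MAD", x$intercept, x$coef_mad))
  if (!is.null(x$coef_dmad)) cat(sprintf(" + %.4g*|dMAD|", x$coef_dmad))
  if (!is.null(x$coef_expfs)) cat(sprintf(" + %.4g*exp(fs)", x$coef_expfs))
  cat("  [mL/kg/min; MAD, dMAD in mg; fs in Hz]\n")
  invisible(x)
}

#' Names of the bundled prediction models
#' @return Character vector of the four bundled model names.
#' @export
bundled_model_names <- function() c("cs_6s", "acdc_6s", "cs_float", "acdc_float")

#' Load a bundled VO2 prediction model
#'
#' Four prediction equations ship with the package, named by training
#' protocol and epoch kind: `cs_6s` and `acdc_6s` (fixed 6 s epochs, MAD
#' only), `cs_float` and `acdc_float` (floating epochs; MAD, |dMAD| and
#' exp(f_s) terms). `cs` models were trained on a progressive constant-speed
#' walking test, `acdc` models on a fast 15 m back-and-forth walk with
#' accelerations, decelerations and turns.
#'
#' @param name One of [bundled_model_names()].
#' @return A [vo2_model()].
#' @export
bundled_model <- function(name) {
  name <- match.arg(name, bundled_model_names())
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "fepoch", mustWork = TRUE)
  read_model(path)
}

#' Read a VO2 model from a JSON file
#' @param path JSON file with fields `name`, `epoch_kind`, `intercept`,
#'   `coef_mad`, optional `coef_dmad`, `coef_expfs`, `training_label`,
#'   `p_values`.
#' @return A [vo2_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vo2_model(intercept = j$intercept, coef_mad = j$coef_mad,
            coef_dmad = j$coef_dmad, coef_expfs = j$coef_expfs,
            name = j$name %||% "unnamed",
            epoch_kind = j$epoch_kind,
            training_label = j$training_label %||% "",
            p_values = if (!is.null(j$p_values)) unlist(j$p_values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a VO2 model to JSON
#' @param model A [vo2_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vo2_model"))
  m <- Filter(Negate(is.null), unclass(model))
  if (!is.null(m$p_values)) m$p_values <- as.list(m$p_values)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

model_terms <- function(model, mad, abs_dmad = NULL, fs = NULL) {
  pred <- model$intercept + model$coef_mad * mad
  if (model$epoch_kind == "floating") {
    if (is.null(abs_dmad) || is.null(fs))
      stop("floating-epoch model requires |dMAD| and step-frequency inputs")
    pred <- pred + model$coef_dmad * abs_dmad + model$coef_expfs * exp(fs)
  }
  pred
}

#' Predict VO2 from a feature summary
#'
#' Evaluates the linear prediction equation at a stage- or test-level
#' [summarize_features()] summary. The summary's epoch kind must match the
#' model's. Predictions are not clamped; a negative result is possible
#' outside the calibrated feature range and triggers a warning.
#'
#' @param object A [vo2_model()].
#' @param summary A `feature_summary`.
#' @param ... Unused.
#' @return Predicted VO2 in mL/kg/min.
#' @export
predict.vo2_model <- function(object, summary, ...) {
  stopifnot(inherits(summary, "feature_summary"))
  if (summary$epoch_kind != object$epoch_kind)
    stop("epoch kind mismatch: model is '", object$epoch_kind,
         "', features are '", summary$epoch_kind, "'")
  pred <- model_terms(object, summary$mean_mad_mg,
                      summary$mean_abs_dmad_mg, summary$mean_fs_hz)
  if (is.finite(pred) && pred < 0)
    warning("predicted VO2 is negative (", format(pred),
            " mL/kg/min); input outside the calibrated range?")
  pred
}

#' Per-epoch VO2 trace
#'
#' Evaluates the model on every epoch of a feature table, preserving epoch
#' timing: each floating epoch supplies its own MAD, |dMAD| and step
#' frequency. Floating epochs without a dMAD value (the first epoch of each
#' bout) yield `NA`.
#'
#' @param model A [vo2_model()].
#' @param features A `feature_table` whose rows of `model$epoch_kind` are
#'   evaluated.
#' @return A data.frame `k`, `start_s`, `end_s`, `vo2` (mL/kg/min).
#' @export
predict_series <- function(model, features) {
  f <- features[features$epoch_kind == model$epoch_kind, , drop = FALSE]
  if (nrow(f) == 0L)
    stop("feature table has no '", model$epoch_kind, "' epochs")
  vo2 <- model_terms(model, f$mad_mg,
                     if (model$epoch_kind == "floating") abs(f$dmad_mg_signed),
                     if (model$epoch_kind == "floating") f$fs_hz)
  data.frame(k = f$k, start_s = f$start_s, end_s = f$end_s, vo2 = vo2)
}

#' Fit a linear VO2 prediction model by ordinary least squares
#'
#' Fits the Gaussian-identity linear model (ordinary least squares with
#' intercept) of VO2 on the epoch-summary features: MAD only for fixed
#' epochs; MAD, |dMAD| and exp(f_s) for floating epochs. Per-coefficient
#' p-values come from the standard t statistics. Training agreement
#' statistics are computed on the fitted values (training bias is zero by
#' construction).
#'
#' @param data A data.frame with columns `mean_mad_mg`, `vo2`, and for the
#'   floating form also `mean_abs_dmad_mg` and `mean_fs_hz`. One row per
#'   observation (stage or test).
#' @param epoch_kind `"fixed6s"` or `"floating"`.
#' @param name,training_label Labels stored in the returned model.
#' @return A [vo2_model()] with `p_values` set and attributes
#'   `training_stats` (an `agreement_stats` object) and `fit` (the `lm`
#'   object).
#' @export
fit_vo2_model <- function(data, epoch_kind = c("fixed6s", "floating"),
                          name = "fitted", training_label = "") {
  epoch_kind <- match.arg(epoch_kind)
  n <- nrow(data)
  if (epoch_kind == "fixed6s") {
    df <- data.frame(vo2 = data$vo2, mad = data$mean_mad_mg)
    p <- 1L
  } else {
    df <- data.frame(vo2 = data$vo2, mad = data$mean_mad_mg,
                     abs_dmad = data$mean_abs_dmad_mg,
                     exp_fs = exp(data$mean_fs_hz))
    p <- 3L
  }
  if (n <= p + 1L)
    stop("need more observations (", n, ") than coefficients (", p + 1L, ")")
  fit <- stats::lm(vo2 ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: a predictor is constant or collinear")
  cf <- stats::coef(fit)
  pv <- summary(fit)$coefficients[, 4]
  model <- vo2_model(
    intercept = cf[["(Intercept)"]], coef_mad = cf[["mad"]],
    coef_dmad = if (epoch_kind == "floating") cf[["abs_dmad"]],
    coef_expfs = if (epoch_kind == "floating") cf[["exp_fs"]],
    name = name, epoch_kind = epoch_kind, training_label = training_label,
    p_values = pv)
  attr(model, "training_stats") <-
    agreement_stats(df$vo2, stats::fitted(fit), method = "training",
                    n_params = p + 1L)
  attr(model, "fit") <- fit
  model
}

#' Agreement statistics between measured and predicted VO2
#'
#' Computes the method-agreement summary for a prediction-vs-measurement
#' pairing: bias (mean of measured minus predicted), the SD of the
#' differences and the Bland-Altman 95% limits of agreement
#' (`bias -/+ 1.96 * SD`), the standard error of estimate (SEE), the
#' coefficient of determination R2, and the mean absolute percentage error
#' (MAPE).
#'
#' Two conventions are implemented. `"validation"` (default): SEE is the
#' n-1 SD of the differences about the bias, and R2 is the squared Pearson
#' correlation between measured and predicted (invariant to a linear
#' recalibration, hence comparable across training and validation sets).
#' `"training"`: SEE is the residual standard error `sqrt(SSE/(n - p))`
#' with `p = n_params` estimated coefficients, and R2 is `1 - SSE/SST`.
#'
#' @param measured,predicted Numeric vectors, VO2 in mL/kg/min. All
#'   measured values must be positive (MAPE is undefined otherwise).
#' @param method `"validation"` or `"training"`.
#' @param n_params Number of estimated coefficients (training SEE only).
#' @return An object of class `agreement_stats`: list with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `see`, `r2`, `mape`.
#' @export
agreement_stats <- function(measured, predicted,
                            method = c("validation", "training"),
                            n_params = 2L) {
  method <- match.arg(method)
  stopifnot(length(measured) == length(predicted))
  n <- length(measured)
  if (n < 2L) stop("need at least 2 paired observations")
  if (any(measured <= 0))
    stop("all measured VO2 values must be positive (MAPE undefined)")
  d <- measured - predicted
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  sse <- sum(d^2)
  if (method == "training") {
    see <- sqrt(sse / (n - n_params))
    r2 <- 1 - sse / sum((measured - mean(measured))^2)
  } else {
    see <- sd_diff
    r2 <- stats::cor(measured, predicted)^2
    if (is.na(r2)) r2 <- 0  # constant predictions carry no information
  }
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 see = see, r2 = r2,
                 mape = 100 * mean(abs(d) / measured)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats>\n")
  cat(sprintf("  n     %6d\n  bias  %8.3f mL/kg/min\n", x$n, x$bias))
  cat(sprintf("  LoA   [%.3f, %.3f] mL/kg/min\n", x$loa_low, x$loa_high))
  cat(sprintf("  SEE   %8.3f mL/kg/min\n  R2    %8.3f\n  MAPE  %8.2f %%\n",
              x$see, x$r2, x$mape))
  invisible(x)
}

#' Validate a model against paired measurements
#'
#' Evaluates the model on each observation's features and returns the
#' validation-convention [agreement_stats()] of the measured-vs-predicted
#' pairing.
#'
#' @param model A [vo2_model()].
#' @param data A data.frame as in [fit_vo2_model()].
#' @return An `agreement_stats` object, with the predictions attached as
#'   attribute `predicted`.
#' @export
validate_model <- function(model, data) {
  pred <- model_terms(model, data$mean_mad_mg,
                      if (model$epoch_kind == "floating") data$mean_abs_dmad_mg,
                      if (model$epoch_kind == "floating") data$mean_fs_hz)
  st <- agreement_stats(data$vo2, pred, method = "validation")
  attr(st, "predicted") <- pred
  st
}
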