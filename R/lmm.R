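# Mixed-effects comparison of thin versus normal wall regions:
#   Y_ij = b0 + b1 * RegionType_ij + (1 | Patient) + (1 | Patient:RegionNo) + e_ij
# fitted by REML, with raw / log / patient-maximum-normalised transforms,
# AIC-based structure comparison and residual diagnostics.

#' Transform specification for the sampled metrics
#'
#' `patient_max` divides each (signed) value by that patient's whole-model
#' maximum of the metric, `log` is the natural logarithm (positive values
#' only), `raw` leaves values untouched. OSI, already bounded and scaled, is
#' always analysed in its original form: requesting a non-raw transform for
#' `osi` is an error.
#'
#' @param method transform applied to every metric not listed in `except`.
#' @param except named character vector of per-metric overrides, e.g.
#'   `c(osi = "raw")` (the default).
#' @return named character vector of class `transform_spec` (filled in
#'   against the table's metric columns by [apply_transform()]).
#' @export
transform_spec <- function(method = c("patient_max", "raw", "log"),
                           except = c(osi = "raw")) {
  method <- match.arg(method)
  structure(list(method = method, except = except), class = "transform_spec")
}

#' Apply a transform to the sampled metric columns
#'
#' @param table a `sample_table`.
#' @param spec a [transform_spec()], or a single method name.
#' @param metrics metric columns to transform; defaults to all columns with
#'   a recorded transform tag.
#' @return the table with transformed columns and updated `transform` tags.
#' @export
apply_transform <- function(table, spec = transform_spec(), metrics = NULL) {
  if (is.character(spec)) spec <- transform_spec(spec)
  tags <- attr(table, "transform")
  if (is.null(tags)) stop("table carries no transform tags; build it with build_sample_table()")
  if (is.null(metrics)) metrics <- names(tags)
  pm <- attr(table, "patient_max")
  for (m in metrics) {
    method <- if (m %in% names(spec$except)) spec$except[[m]] else spec$method
    if (m == "osi" && method != "raw")
      stop("OSI is analysed in its original form; refusing transform '", method, "'")
    if (tags[[m]] != "raw")
      stop("column '", m, "' already transformed ('", tags[[m]], "')")
    if (method == "raw") next
    if (method == "log") {
      if (any(table[[m]] <= 0, na.rm = TRUE))
        stop("log transform requested for '", m, "' but it contains values <= 0")
      table[[m]] <- log(table[[m]])
    } else if (method == "patient_max") {
      if (is.null(pm)) stop("patient_max transform needs the per-patient maxima attribute")
      mx <- pm[as.character(table$patient_id), m]
      if (any(mx == 0)) stop("patient maximum of '", m, "' is zero for some patient")
      table[[m]] <- table[[m]] / mx
    } else stop("unknown transform method '", method, "'")
    tags[[m]] <- method
  }
  attr(table, "transform") <- tags
  table
}

#' Fit the regional linear mixed-effects model
#'
#' Model 2 (the final structure): fixed region-type effect plus random
#' intercepts for patient and for region nested within patient. Model 1:
#' fixed region-type effect plus random intercepts for patient and for
#' region type. Fitted by REML via `lmerTest`; the reference level is
#' `normal`, so the fixed coefficient is the thin-minus-normal difference.
#' The 95% CI is Wald (estimate +/- 1.96 SE); the p-value uses the
#' Satterthwaite degrees-of-freedom approximation.
#'
#' @param table a `sample_table` (or any data.frame with `patient_id`,
#'   `region_type`, `region_no` and the metric column).
#' @param metric name of the response column.
#' @param model `"model2"` (default) or `"model1"`.
#' @return object of class `aneuwall_lmm`: list with `beta0`, `beta1`,
#'   `se`, `ci` (length 2), `p_value`, `var_patient`, `var_region`,
#'   `var_residual`, `aic`, `n_obs`, `singular`, `residuals`, `fitted`,
#'   `metric`, `model`, `transform`, and the underlying `fit`.
#' @export
fit_lmm <- function(table, metric, model = c("model2", "model1")) {
  model <- match.arg(model)
  if (!metric %in% names(table)) stop("metric column '", metric, "' not found")
  if (nlevels(droplevels(table$patient_id)) < 2L) stop("need at least 2 patients")
  if (nlevels(droplevels(table$region_type)) < 2L)
    stop("both region types must be present")
  dat <- data.frame(y = table[[metric]],
                    patient_id = droplevels(table$patient_id),
                    region_type = stats::relevel(droplevels(table$region_type),
                                                 ref = "normal"),
                    region_no = factor(table$region_no))
  if (anyNA(dat$y)) stop("response contains undefined values")
  form <- if (model == "model2") {
    y ~ region_type + (1 | patient_id) + (1 | patient_id:region_no)
  } else {
    y ~ region_type + (1 | patient_id) + (1 | region_type)
  }
  msgs <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = dat, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    stop("mixed-model fit did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  co <- tryCatch(summary(fit)$coefficients,
                 error = function(e) cbind(lme4::fixef(fit), NA, NA, NA, NA))
  beta0 <- co[1, 1]; beta1 <- co[2, 1]; se <- co[2, 2]
  p <- if (ncol(co) >= 5) co[2, 5] else NA_real_
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { i <- match(g, vc$grp); if (is.na(i)) NA_real_ else vc$vcov[i] }
  tags <- attr(table, "transform")
  structure(list(
    beta0 = beta0, beta1 = beta1, se = se,
    ci = beta1 + c(-1, 1) * stats::qnorm(0.975) * se,
    p_value = p,
    var_patient = getv("patient_id"),
    var_region = if (model == "model2") getv("patient_id:region_no") else getv("region_type"),
    var_residual = getv("Residual"),
    aic = stats::AIC(fit),
    n_obs = nrow(dat),
    singular = lme4::isSingular(fit),
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    metric = metric, model = model, messages = msgs,
    transform = if (!is.null(tags) && metric %in% names(tags)) tags[[metric]] else NA_character_,
    fit = fit), class = "aneuwall_lmm")
}

#' @export
print.aneuwall_lmm <- function(x, ...) {
  cat(sprintf("Regional LMM (%s) for %s [%s transform]\n", x$model, x$metric,
              x$transform))
  cat(sprintf("  thin - normal: %.4g  (95%% CI %.4g .. %.4g, p = %.3g)\n",
              x$beta1, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  intercept (normal mean): %.4g\n", x$beta0))
  cat(sprintf("  variances: patient %.3g | region-in-patient %.3g | residual %.3g\n",
              x$var_patient, x$var_region, x$var_residual))
  cat(sprintf("  AIC %.1f on %d rows%s\n", x$aic, x$n_obs,
              if (isTRUE(x$singular)) " (singular random effects)" else ""))
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' @param results named list of `aneuwall_lmm` fits of the same rows (equal
#'   observation counts are enforced; AIC is not comparable otherwise).
#' @return data.frame sorted by ascending AIC with `delta_aic` relative to
#'   the best model.
#' @export
compare_models_aic <- function(results) {
  if (length(results) < 2L) stop("need at least two fitted models")
  n <- vapply(results, function(r) r$n_obs, numeric(1))
  if (length(unique(n)) != 1L)
    stop("models were fitted on differing row counts; AIC is not comparable")
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r)
      paste(r$metric, r$transform, r$model, sep = "/"), character(1))
  aic <- vapply(results, function(r) r$aic, numeric(1))
  out <- data.frame(model = names(results), aic = aic,
                    delta_aic = aic - min(aic))
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out
}

#' Residual diagnostics for a fitted regional model
#'
#' Emits the four diagnostic datasets used to assess normality,
#' homoscedasticity and independence — Q-Q quantile pairs, residuals versus
#' fitted values, a residual histogram and residuals by observation order —
#' plus the Shapiro-Wilk statistic as a numeric summary.
#'
#' @param result an `aneuwall_lmm`.
#' @param n_bins histogram bin count.
#' @return list of class `lmm_diagnostics` with `qq` (data.frame
#'   `theoretical`, `sample`), `resid_fitted`, `histogram`, `by_order`,
#'   `shapiro_w`, `shapiro_p`.
#' @export
residual_diagnostics <- function(result, n_bins = 32L) {
  r <- result$residuals
  qq <- stats::qqnorm(scale(r)[, 1], plot.it = FALSE)
  hh <- hist(r, breaks = n_bins, plot = FALSE)
  sw <- stats::shapiro.test(if (length(r) > 5000) sample(r, 5000) else r)
  structure(list(
    qq = data.frame(theoretical = sort(qq$x), sample = sort(qq$y)),
    resid_fitted = data.frame(fitted = result$fitted, residual = r),
    histogram = data.frame(mid = hh$mids, count = hh$counts),
    by_order = data.frame(order = seq_along(r), residual = r),
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value),
    class = "lmm_diagnostics")
}

#' Interpret a patient-maximum-normalised fit
#'
#' For fits on patient-maximum-normalised values the fixed coefficient is
#' directly a fraction of each patient's maximum: this reports it as a
#' percentage, together with the implied thin-region mean
#' (intercept + coefficient) and the CI on both scales.
#'
#' @param result an `aneuwall_lmm` fitted to a `patient_max`-transformed
#'   metric (anything else is an error).
#' @return list of class `effect_report`: `metric`, `normal_mean` (b0),
#'   `difference` (b1), `thin_mean` (b0 + b1), `pct_of_patient_max`
#'   (100 * b1), `ci`, `ci_pct`, `p_value`.
#' @export
summarize_effects <- function(result) {
  if (!identical(result$transform, "patient_max"))
    stop("effect summary on the %%-of-patient-maximum scale requires a patient_max fit; got '",
         result$transform, "'")
  structure(list(metric = result$metric,
                 normal_mean = result$beta0,
                 difference = result$beta1,
                 thin_mean = result$beta0 + result$beta1,
                 pct_of_patient_max = 100 * result$beta1,
                 ci = result$ci,
                 ci_pct = 100 * result$ci,
                 p_value = result$p_value), class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("%s: normal %.3f, thin %.3f (difference %+.3f = %+.1f%% of patient max; 95%% CI %.3f .. %.3f, p = %.3g)\n",
              x$metric, x$normal_mean, x$thin_mean, x$difference,
              x$pct_of_patient_max, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' Fit all six metrics with the analysis defaults
#'
#' Normalises every metric by the patient-specific maximum except OSI (kept
#' raw) and fits Model 2 per metric.
#'
#' @param table a raw `sample_table`.
#' @param model model structure passed to [fit_lmm()].
#' @return named list of `aneuwall_lmm` fits.
#' @export
fit_all_metrics <- function(table, model = "model2") {
  tab <- apply_transform(table, transform_spec("patient_max", except = c(osi = "raw")))
  metrics <- names(attr(tab, "transform"))
  stats::setNames(lapply(metrics, function(m) fit_lmm(tab, m, model = model)),
                  metrics)
}
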