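#' Collapse triplicate measurements to one value per visit
#'
#' Longitudinal ultrasound protocols take up to three blinded replicate
#' measurements per visit; two-level models use one value per (subject,
#' visit), obtained here by the mean (default), the median, or random
#' selection of one available replicate.
#'
#' @param records longitudinal data frame with columns `id`, `visit`,
#'   `replicate`, `ga_weeks`, `value` (`value` may be `NA` for missing
#'   replicates).
#' @param method `"mean"`, `"random"` or `"median"`.
#' @param seed integer seed, required for `method = "random"`.
#' @return Data frame with one row per (subject, visit): columns `id`,
#'   `visit`, `ga_weeks`, `value`, `n_replicates`. Visits with no
#'   non-missing replicate are dropped (count reported via message).
#' @export
collapse_triplicates <- function(records, method = c("mean", "random", "median"),
                                 seed = NULL) {
  method <- match.arg(method)
  records <- validate_longitudinal(records)
  if (method == "random") {
    if (is.null(seed)) stop("'seed' is required for method = \"random\"",
                            call. = FALSE)
    set.seed(seed)
  }
  key <- interaction(records$id, records$visit, drop = TRUE)
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    switch(method,
           mean = mean(v),
           median = stats::median(v),
           random = v[sample.int(length(v), 1L)])
  }
  value <- tapply(records$value, key, agg)
  nrep <- tapply(records$value, key, function(v) sum(!is.na(v)))
  first <- !duplicated(key)
  out <- data.frame(
    id = records$id[first], visit = records$visit[first],
    ga_weeks = records$ga_weeks[first],
    value = as.numeric(value[as.character(key[first])]),
    n_replicates = as.integer(nrep[as.character(key[first])]),
    stringsAsFactors = FALSE)
  dropped <- sum(is.na(out$value))
  if (dropped > 0) {
    message(sprintf("dropped %d visit(s) with no non-missing replicate", dropped))
    out <- out[!is.na(out$value), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fit a multilevel model to longitudinal growth data
#'
#' Maximum-likelihood (not REML, so deviances are comparable across
#' fixed-effect structures) linear mixed models with a fractional-polynomial
#' fixed mean in gestational age:
#'
#' * `ri2`  two-level random intercept: subject-level intercept deviation,
#'   one collapsed value per visit.
#' * `ris2` two-level random intercept and slope: subject-level intercept and
#'   GA-slope deviations, collapsed values.
#' * `ris3` three-level random intercept and slope: subject-level intercept
#'   and slope, a visit-level intercept, and the triplicate-level residual;
#'   takes the full replicate records.
#'
#' The random slope multiplies raw gestational age by default;
#' `center_ga = TRUE` centers it (a reparameterization of the
#' intercept/slope covariance only).
#'
#' @param records collapsed two-level records (`ri2`/`ris2`, from
#'   [collapse_triplicates()]) or full longitudinal records (`ris3`).
#' @param model_kind `"ri2"`, `"ris2"` or `"ris3"`.
#' @param fixed_powers FP power tuple for the fixed mean curve (default
#'   `c(2, 2)`).
#' @param center_ga center gestational age in the random slope term.
#' @return Object of class `"multilevel_fit"`: `fixed` (an [fp_spec()]),
#'   variance components `var_intercept`, `var_slope`, `cov_int_slope`,
#'   `var_visit_level`, `var_residual`, `deviance` (-2 log-likelihood),
#'   `n_obs`, `model_kind`, `boundary` flag, `ga_range` and the underlying
#'   `lme4` fit.
#' @export
fit_multilevel <- function(records, model_kind = c("ri2", "ris2", "ris3"),
                           fixed_powers = c(2, 2), center_ga = FALSE) {
  model_kind <- match.arg(model_kind)
  fixed_powers <- sort(as.numeric(fixed_powers))
  check_fp_powers(fixed_powers)
  needed <- c("id", "ga_weeks", "value")
  if (model_kind == "ris3") needed <- c(needed, "visit")
  if (!all(needed %in% names(records))) {
    stop(sprintf("records must have columns: %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  records <- records[!is.na(records$value), , drop = FALSE]
  d <- data.frame(
    y = as.numeric(records$value),
    ga = as.numeric(records$ga_weeks),
    subject = factor(records$id))
  if (any(d$ga <= 0)) stop("gestational ages must be positive", call. = FALSE)
  ga_slope <- if (center_ga) d$ga - mean(d$ga) else d$ga
  d$ga_s <- ga_slope
  B <- fp_basis(d$ga, fixed_powers)
  colnames(B) <- paste0("fp", seq_len(ncol(B)))
  d <- cbind(d, B)
  fp_terms <- paste(colnames(B), collapse = " + ")
  form <- switch(model_kind,
    ri2  = sprintf("y ~ %s + (1 | subject)", fp_terms),
    ris2 = sprintf("y ~ %s + (1 + ga_s | subject)", fp_terms),
    ris3 = {
      d$visit_id <- factor(paste(records$id, records$visit, sep = ":"))
      sprintf("y ~ %s + (1 + ga_s | subject) + (1 | visit_id)", fp_terms)
    })
  fit <- lme4::lmer(stats::as.formula(form), data = d, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                check.scaleX = "ignore",
                                                calc.derivs = FALSE))
  vc <- lme4::VarCorr(fit)
  subj <- vc$subject
  var_int <- subj[1, 1]
  var_slope <- if (model_kind != "ri2") subj[2, 2] else 0
  cov_is <- if (model_kind != "ri2") subj[1, 2] else 0
  var_visit <- if (model_kind == "ris3") vc$visit_id[1, 1] else 0
  fixef <- lme4::fixef(fit)
  structure(list(
    fixed = fp_spec(fixed_powers, unname(fixef)),
    var_intercept = var_int, var_slope = var_slope, cov_int_slope = cov_is,
    var_visit_level = var_visit, var_residual = stats::sigma(fit)^2,
    deviance = as.numeric(-2 * stats::logLik(fit)),
    n_obs = nrow(d), model_kind = model_kind,
    center_ga = center_ga, ga_center = if (center_ga) mean(d$ga) else 0,
    boundary = lme4::isSingular(fit), ga_range = range(d$ga),
    lme4_fit = fit
  ), class = "multilevel_fit")
}

#' @export
print.multilevel_fit <- function(x, ...) {
  cat(sprintf("Multilevel model (%s), n = %d, ML deviance %.1f%s\n",
              x$model_kind, x$n_obs, x$deviance,
              if (x$boundary) " [variance at boundary]" else ""))
  cat(sprintf("  fixed mean: FP powers (%s)\n",
              paste(x$fixed$powers, collapse = ", ")))
  cat(sprintf("  var(intercept) %.4g, var(slope) %.4g, cov %.4g\n",
              x$var_intercept, x$var_slope, x$cov_int_slope))
  if (x$model_kind == "ris3") {
    cat(sprintf("  var(visit) %.4g\n", x$var_visit_level))
  }
  cat(sprintf("  var(residual) %.4g\n", x$var_residual))
  invisible(x)
}

## model-implied total variance of a single measurement at GA t
multilevel_total_var <- function(fit, ga) {
  t_s <- ga - fit$ga_center
  v <- fit$var_intercept + 2 * fit$cov_int_slope * t_s +
    fit$var_slope * t_s^2 + fit$var_visit_level + fit$var_residual
  if (any(v < 0)) {
    stop("model-implied total variance is negative; components are inconsistent",
         call. = FALSE)
  }
  v
}

#' Marginal SD curve of a multilevel fit
#'
#' The total SD of a single measurement at each gestational age is assembled
#' from the variance components (intercept + 2*cov*t + slope*t^2 +
#' visit-level + residual, as present in the model), evaluated on a grid over
#' the fitted range and smoothed as a fractional polynomial of the requested
#' degree — the SD curve used for centile construction.
#'
#' @param fit a [fit_multilevel()] object.
#' @param sd_degree FP degree for the SD curve (default 3).
#' @param grid_length grid resolution (default 101).
#' @return An [fp_spec()] for the SD as a function of gestational age.
#' @export
marginal_sd_curve <- function(fit, sd_degree = 3, grid_length = 101) {
  stopifnot(inherits(fit, "multilevel_fit"))
  grid <- seq(fit$ga_range[1], fit$ga_range[2], length.out = grid_length)
  sd_grid <- sqrt(multilevel_total_var(fit, grid))
  fit_fp(grid, sd_grid, degree = sd_degree)
}

#' Centile chart from a multilevel fit
#'
#' Combines the fixed fractional-polynomial mean with the marginal SD curve
#' into a normal-theory chart object usable with [chart_table()],
#' [write_chart()] and [multilevel_centile()].
#'
#' @inheritParams marginal_sd_curve
#' @return Object of class `"multilevel_chart"` with `mean_curve` and
#'   `sd_curve` components.
#' @export
multilevel_chart <- function(fit, sd_degree = 3) {
  structure(list(mean_curve = fit$fixed,
                 sd_curve = marginal_sd_curve(fit, sd_degree),
                 model_kind = fit$model_kind,
                 ga_range = fit$ga_range),
            class = "multilevel_chart")
}

#' @rdname multilevel_chart
#' @param chart a `"multilevel_chart"` object.
#' @param ga gestational age(s) in exact weeks.
#' @param centile centile(s) in percent.
#' @export
multilevel_centile <- function(chart, ga, centile) {
  stopifnot(inherits(chart, "multilevel_chart"))
  z <- stats::qnorm(centile / 100)
  val <- predict(chart$mean_curve, ga) + z * predict(chart$sd_curve, ga)
  flag_extrapolation(val, ga, chart$ga_range)
}

## ---- published fetal head circumference standard -------------------------

#' Published fetal head circumference chart equations
#'
#' The closed-form international FHC standard: the mean is a second-order
#' fractional polynomial with powers (2, 2) of exact gestational age in
#' weeks,
#' `-28.2849 + 1.69267*GA^2 - 0.397485*GA^2*log(GA)`,
#' and the SD a third-order fractional polynomial with powers (3, 3, 3),
#' `1.98735 + 0.0136772*GA^3 - 0.00726264*GA^3*log(GA) +
#'  0.000976253*GA^3*log(GA)^2`,
#' both in millimetres, natural logarithms, valid for 14-42 weeks.
#'
#' @return Object of class `"published_fhc_chart"` with `mean_curve` and
#'   `sd_curve` [fp_spec()] components and `ga_range = c(14, 42)`.
#' @export
published_fhc_chart <- function() {
  structure(list(
    mean_curve = fp_spec(c(2, 2), c(-28.2849, 1.69267, -0.397485)),
    sd_curve = fp_spec(c(3, 3, 3),
                       c(1.98735, 0.0136772, -0.00726264, 0.000976253)),
    units = "mm", ga_range = c(14, 42)
  ), class = c("published_fhc_chart", "multilevel_chart"))
}

#' Published FHC centile and Z-score
#'
#' Evaluate the published fetal head circumference standard equations (see
#' [published_fhc_chart()]): `mean(ga) + z * sd(ga)` in mm, and its inverse.
#' Gestational ages outside 14-42 weeks are flagged with a warning.
#'
#' @param ga gestational age(s), exact weeks.
#' @param centile centile(s) in percent.
#' @return Millimetres ([published_fhc()]) or Z-scores
#'   ([published_fhc_zscore()]).
#' @examples
#' published_fhc(40, 50) # about 334 mm
#' @export
published_fhc <- function(ga, centile) {
  multilevel_centile(published_fhc_chart(), ga, centile)
}

#' @rdname published_fhc
#' @param value measured FHC in mm.
#' @export
published_fhc_zscore <- function(ga, value) {
  chart <- published_fhc_chart()
  z <- (value - predict(chart$mean_curve, ga)) / predict(chart$sd_curve, ga)
  flag_extrapolation(z, ga, chart$ga_range)
}
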