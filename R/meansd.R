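#' Fit the fractional-polynomial mean-SD centile model
#'
#' Normal-theory centile construction: the age-specific mean is fitted by a
#' best-power fractional polynomial of gestational age; the age-specific SD
#' is obtained by regressing the absolute residuals on gestational age
#' (another fractional polynomial) and scaling the fitted curve by
#' `sqrt(pi/2)`, the half-normal correction (if the residuals are normal,
#' `E|r| = sd * sqrt(2/pi)`). Optionally the mean is refitted once with
#' weights `1 / sd^2` and the SD re-estimated.
#'
#' @param records data frame with columns `ga_weeks` (positive, exact weeks)
#'   and `value`, one row per subject (cross-sectional design).
#' @param mean_degree FP degree for the mean curve (default 2).
#' @param sd_degree FP degree for the SD curve (default 1; up to 3).
#' @param reweight logical; perform exactly one weighted refit of the mean
#'   with weights `1/sd^2` (default `FALSE`; the effect is typically small).
#' @param transform `"none"`, `"log"`, or `"shifted_log"`; with
#'   `"shifted_log"` the model is fitted to `log(value + shift_k)` and
#'   centiles are back-transformed.
#' @param shift_k shift constant for `transform = "shifted_log"`.
#' @return Object of class `"mean_sd_model"` with components `mean_curve` and
#'   `sd_curve` ([fp_spec()] objects, the latter already including the
#'   `sqrt(pi/2)` scaling in its fitted use), `sd_scale`, `transform`,
#'   `shift_k`, `n_obs`, `ga_range`.
#' @examples
#' set.seed(1)
#' ga <- runif(500, 33, 42)
#' d <- data.frame(ga_weeks = ga, value = rnorm(500, 1000 + 60 * ga, 50))
#' m <- fit_mean_sd(d)
#' normal_centile(m, 40, 50)
#' @export
fit_mean_sd <- function(records, mean_degree = 2, sd_degree = 1,
                        reweight = FALSE,
                        transform = c("none", "log", "shifted_log"),
                        shift_k = 0) {
  transform <- match.arg(transform)
  records <- validate_crosssec(records)
  if (nrow(records) < 30L) {
    stop("at least 30 records are required to model the mean and SD",
         call. = FALSE)
  }
  ga <- records$ga_weeks
  y <- switch(transform,
              none = records$value,
              log = log(records$value),
              shifted_log = log(records$value + shift_k))
  if (any(!is.finite(y))) {
    stop("transformed values are not finite; check 'transform'/'shift_k'",
         call. = FALSE)
  }
  sd_scale <- sqrt(pi / 2)
  fit_once <- function(w) {
    mean_fit <- fit_fp(ga, y, weights = w, degree = mean_degree)
    absres <- abs(y - predict(mean_fit, ga))
    sd_fit <- fit_fp(ga, absres, degree = sd_degree)
    list(mean = mean_fit, sd = sd_fit)
  }
  fits <- fit_once(NULL)
  if (isTRUE(reweight)) {
    sd_hat <- pmax(sd_scale * predict(fits$sd, ga), 1e-10)
    fits <- fit_once(1 / sd_hat^2) # exactly one reweighting pass
  }
  model <- structure(
    list(mean_curve = fits$mean, sd_curve = fits$sd, sd_scale = sd_scale,
         transform = transform, shift_k = shift_k,
         n_obs = nrow(records), ga_range = range(ga)),
    class = "mean_sd_model"
  )
  ## the SD curve must stay non-negative over the observed GA range
  ## (a numerically-zero SD is allowed: degenerate noiseless data)
  grid <- seq(model$ga_range[1], model$ga_range[2], length.out = 201)
  sd_grid <- model_sd(model, grid)
  tol <- 1e-8 * (stats::sd(y) + 1e-12)
  if (any(sd_grid < -tol)) {
    bad <- range(grid[sd_grid < -tol])
    stop(sprintf(
      "fitted SD is non-positive between %.2f and %.2f weeks; consider a different sd_degree or a transformation",
      bad[1], bad[2]), call. = FALSE)
  }
  model
}

model_mean <- function(model, ga) predict(model$mean_curve, ga)
model_sd <- function(model, ga) model$sd_scale * predict(model$sd_curve, ga)

flag_extrapolation <- function(value, ga, ga_range) {
  outside <- ga < ga_range[1] | ga > ga_range[2]
  if (any(outside)) {
    warning(sprintf("%d gestational age value(s) outside the fitted range [%.2f, %.2f]; centiles are extrapolated",
                    sum(outside), ga_range[1], ga_range[2]), call. = FALSE)
    attr(value, "extrapolated") <- outside
  }
  value
}

#' Normal-theory centile from a mean-SD model
#'
#' Evaluates `mean(ga) + z * sd(ga)` with `z` the standard-normal quantile of
#' the requested centile (z is about 1.88 for the 97th, -1.88 for the 3rd).
#' Gestational ages outside the fitted range are allowed but flagged via an
#' `"extrapolated"` attribute and a warning.
#'
#' @param model a [fit_mean_sd()] model.
#' @param ga gestational age(s), exact weeks.
#' @param centile centile(s) in percent, strictly between 0 and 100.
#' @return Numeric vector of measurement values (back-transformed if the
#'   model was fitted on a log scale).
#' @export
normal_centile <- function(model, ga, centile) {
  stopifnot(inherits(model, "mean_sd_model"))
  if (any(centile <= 0 | centile >= 100)) {
    stop("'centile' must be strictly between 0 and 100", call. = FALSE)
  }
  z <- stats::qnorm(centile / 100)
  val <- model_mean(model, ga) + z * model_sd(model, ga)
  val <- switch(model$transform,
                none = val,
                log = exp(val),
                shifted_log = exp(val) - model$shift_k)
  flag_extrapolation(val, ga, model$ga_range)
}

#' Z-score (SD score) from a mean-SD model
#'
#' @inheritParams normal_centile
#' @param y measurement value(s) on the original scale.
#' @return `(y' - mean(ga)) / sd(ga)` where `y'` is `y` on the model's
#'   fitting scale.
#' @export
normal_zscore <- function(model, ga, y) {
  stopifnot(inherits(model, "mean_sd_model"))
  yt <- switch(model$transform,
               none = y,
               log = log(y),
               shifted_log = log(y + model$shift_k))
  s <- model_sd(model, ga)
  if (any(s <= 0)) stop("fitted SD is non-positive at the requested gestational age",
                        call. = FALSE)
  z <- (yt - model_mean(model, ga)) / s
  flag_extrapolation(z, ga, model$ga_range)
}

#' @export
print.mean_sd_model <- function(x, ...) {
  cat("Fractional-polynomial mean-SD centile model\n")
  cat(sprintf("  n = %d, GA range [%.2f, %.2f] weeks, transform = %s\n",
              x$n_obs, x$ga_range[1], x$ga_range[2], x$transform))
  cat(sprintf("  mean: FP%d powers (%s)\n", x$mean_curve$degree,
              paste(x$mean_curve$powers, collapse = ", ")))
  cat(sprintf("  SD:   sqrt(pi/2) x FP%d powers (%s) of |residual|\n",
              x$sd_curve$degree, paste(x$sd_curve$powers, collapse = ", ")))
  invisible(x)
}
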