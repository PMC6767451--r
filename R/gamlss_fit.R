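#' Fit an LMS-type distributional centile model
#'
#' Each distribution parameter (mu, sigma, and where the family has them nu
#' and tau) is modelled as a smooth function of gestational age — a constant,
#' a fractional polynomial, or a penalized cubic spline at a target edf — and
#' the penalized likelihood is maximized by cyclic updates: each parameter's
#' curve coefficients are refitted (quasi-Newton) holding the others fixed,
#' until the penalized deviance changes by less than `tol` or `max_cycles`
#' cycles are exhausted. sigma and tau (and the positive skew/power nu of
#' the PE, SEP3 and ST3 families) are fitted on a log link; mu and the
#' Box-Cox power nu on the identity link.
#'
#' The family/curve combinations express the classical chart methods: `NO`
#' with FP curves is the fractional-polynomial method on a distributional
#' footing, `BCCG` with spline curves is the LMS method, `BCT` is LMST and
#' `BCPE` is LMSP.
#'
#' @param records cross-sectional data frame with `ga_weeks` and `value`
#'   columns (one row per subject).
#' @param family distribution family, see [family_functions].
#' @param curve_specs named list of [curve_spec()] objects for `mu`, `sigma`
#'   and (as applicable) `nu`, `tau`. Omitted parameters get a constant
#'   curve; `mu` defaults to a pspline with edf 4.
#' @param tol convergence tolerance on the penalized deviance (default 1e-4).
#' @param max_cycles cycle cap (default 500).
#' @param trace logical; print the deviance per cycle.
#' @return Object of class `"centile_model"`: fitted curves, family,
#'   `global_deviance` (-2 max log-likelihood, unpenalized), `df_total`,
#'   `ga_range`, `n_obs`, and a `report` (see [fit_report()]).
#' @examples
#' set.seed(7)
#' ga <- runif(400, 14, 42)
#' y <- family_random("NO", list(mu = 100 + 5 * ga, sigma = 8), 400)
#' m <- fit_centile_model(data.frame(ga_weeks = ga, value = y), "NO",
#'                        list(mu = curve_spec("fp", powers = 1)))
#' model_centile(m, 28, 50)
#' @export
fit_centile_model <- function(records, family,
                              curve_specs = list(),
                              tol = 1e-4, max_cycles = 500, trace = FALSE) {
  family <- match.arg(family, FAMILIES)
  records <- validate_crosssec(records)
  ga <- records$ga_weeks
  y <- records$value
  n <- length(y)
  par_names <- family_par_names(family)
  if (!all(names(curve_specs) %in% par_names)) {
    stop(sprintf("curve_specs names must be among: %s",
                 paste(par_names, collapse = ", ")), call. = FALSE)
  }
  specs <- default_curve_specs(family)
  specs[names(curve_specs)] <- curve_specs
  specs <- specs[par_names]
  links <- param_links(family)

  curves <- lapply(specs, build_curve, ga = ga)
  theta <- init_theta(family, curves, ga, y)

  eval_eta <- function() {
    lapply(par_names, function(p)
      as.numeric(curves[[p]]$B %*% theta[[p]]))
  }
  eta_to_params <- function(eta) {
    out <- lapply(seq_along(par_names), function(i)
      if (links[i] == "log") exp(eta[[i]]) else eta[[i]])
    names(out) <- par_names
    out
  }
  penalty <- function(th) {
    sum(vapply(par_names, function(p)
      curves[[p]]$lambda * as.numeric(crossprod(th[[p]], curves[[p]]$P %*% th[[p]])),
      numeric(1)))
  }
  neg2ll <- function(params) {
    if (family %in% c("BCCG", "BCT", "BCPE") && any(params$mu <= 0)) return(Inf)
    ld <- tryCatch(family_loglik(family, params, y), error = function(e) -Inf)
    if (!all(is.finite(ld))) return(Inf)
    -2 * sum(ld)
  }
  pen_dev <- function() {
    params <- eta_to_params(eval_eta())
    neg2ll(params) + penalty(theta)
  }

  dev <- pen_dev()
  if (!is.finite(dev)) stop("initialization gave a non-finite deviance", call. = FALSE)
  dev_trace <- dev
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    for (p in par_names) {
      idx <- match(p, par_names)
      obj <- function(th_p) {
        theta_try <- theta
        theta_try[[p]] <- th_p
        eta <- lapply(par_names, function(q)
          as.numeric(curves[[q]]$B %*% theta_try[[q]]))
        d <- neg2ll(eta_to_params(eta)) + penalty(theta_try)
        if (!is.finite(d)) 1e10 else d
      }
      opt <- stats::optim(theta[[p]], obj, method = "BFGS",
                          control = list(maxit = 60, reltol = 1e-10))
      if (opt$value <= dev) theta[[p]] <- opt$par
    }
    new_dev <- pen_dev()
    dev_trace <- c(dev_trace, new_dev)
    if (trace) message(sprintf("cycle %d: penalized deviance %.6f", cycle, new_dev))
    if (abs(dev - new_dev) < tol) { converged <- TRUE; dev <- new_dev; break }
    dev <- new_dev
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "centile model did not converge in %d cycles (last penalized deviance %.6f)",
      max_cycles, dev))
    cond$deviance_trace <- dev_trace
    stop(cond)
  }

  global_deviance <- neg2ll(eta_to_params(eval_eta()))
  fitted_curves <- lapply(par_names, function(p) {
    cv <- curves[[p]]
    list(spec = cv$spec, ga_range = cv$ga_range, knots = cv$knots,
         lambda = cv$lambda, edf = cv$edf,
         coefficients = unname(theta[[p]]),
         link = links[[match(p, par_names)]])
  })
  names(fitted_curves) <- par_names
  model <- structure(
    list(family = family, curves = fitted_curves,
         n_obs = n, global_deviance = global_deviance,
         df_total = sum(vapply(curves, `[[`, numeric(1), "edf")),
         ga_range = range(ga)),
    class = "centile_model"
  )
  model$report <- fit_report(model, records)
  model
}

## log-density without the validation layer (speed inside the optimizer)
family_loglik <- function(family, params, y) {
  family_pdf(family, params, y, log = TRUE)
}

param_links <- function(family) {
  nm <- family_par_names(family)
  vapply(nm, function(p) {
    if (p %in% c("sigma", "tau")) return("log")
    if (p == "nu" && family %in% c("PE", "SEP3", "ST3")) return("log")
    "identity"
  }, character(1))
}

default_curve_specs <- function(family) {
  nm <- family_par_names(family)
  out <- lapply(nm, function(p)
    if (p == "mu") curve_spec("pspline", edf = 4) else curve_spec("constant"))
  names(out) <- nm
  out
}

## starting coefficients: mu from a least-squares fit of y on its basis,
## sigma from the residual SD (as a CV for Box-Cox families), shape
## parameters at their normal-like values
init_theta <- function(family, curves, ga, y) {
  par_names <- names(curves)
  links <- param_links(family)
  theta <- list()
  Bmu <- curves$mu$B
  fit <- stats::lm.fit(Bmu, y)
  mu_hat <- as.numeric(Bmu %*% fit$coefficients)
  if (family %in% c("BCCG", "BCT", "BCPE") && any(mu_hat <= 0)) {
    fit$coefficients[] <- 0
    fit$coefficients[1] <- stats::median(y)
    if (curves$mu$spec$kind == "pspline") fit$coefficients[] <- stats::median(y)
    mu_hat <- as.numeric(Bmu %*% fit$coefficients)
  }
  theta$mu <- unname(fit$coefficients)
  s0 <- stats::sd(y - mu_hat)
  if (family %in% c("BCCG", "BCT", "BCPE")) s0 <- s0 / mean(abs(mu_hat))
  s0 <- max(s0, 1e-6)
  theta$sigma <- const_coef(curves$sigma, log(s0))
  if ("nu" %in% par_names) {
    nu0 <- switch(family, PE = 2, SEP3 = 1, ST3 = 1, 1) # Box-Cox power 1
    val <- if (links[["nu"]] == "log") log(nu0) else nu0
    theta$nu <- const_coef(curves$nu, val)
  }
  if ("tau" %in% par_names) {
    tau0 <- switch(family, BCT = 10, ST3 = 10, BCPE = 2, SEP3 = 2, 2)
    theta$tau <- const_coef(curves$tau, log(tau0))
  }
  theta[par_names]
}

## coefficients representing a constant value c on a basis: B-spline bases
## (rows summing to 1) take rep(c, k); bases with an explicit intercept take
## c in the first slot
const_coef <- function(curve, value) {
  k <- ncol(curve$B)
  if (curve$spec$kind == "pspline") return(rep(value, k))
  c(value, rep(0, k - 1L))
}

#' Evaluate the fitted parameter curves of a centile model
#'
#' @param model a [fit_centile_model()] object.
#' @param ga gestational age(s), exact weeks.
#' @return Named list of parameter vectors (`mu`, `sigma`, ...), one value
#'   per element of `ga`.
#' @export
model_params <- function(model, ga) {
  stopifnot(inherits(model, "centile_model"))
  out <- lapply(model$curves, function(cv) {
    B <- curve_basis_at(cv, ga)
    eta <- as.numeric(B %*% cv$coefficients)
    if (cv$link == "log") exp(eta) else eta
  })
  names(out) <- names(model$curves)
  out
}

#' Centile values from a fitted centile model
#'
#' @inheritParams model_params
#' @param centile centile(s) in percent.
#' @return Measurement value(s): the family quantile at the age-specific
#'   fitted parameters.
#' @export
model_centile <- function(model, ga, centile) {
  if (any(centile <= 0 | centile >= 100)) {
    stop("'centile' must be strictly between 0 and 100", call. = FALSE)
  }
  params <- model_params(model, ga)
  val <- family_quantile(model$family, params, centile / 100)
  flag_extrapolation(val, ga, model$ga_range)
}

#' Z-scores (SDS) from a fitted centile model
#'
#' The measurement's position in the fitted age-conditional distribution,
#' mapped to the standard normal scale: `qnorm(F(y; theta(ga)))`.
#'
#' @inheritParams model_params
#' @param y measurement value(s).
#' @return Z-score(s).
#' @export
model_sds <- function(model, ga, y) {
  params <- model_params(model, ga)
  u <- family_cdf(model$family, params, y)
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  stats::qnorm(u)
}

#' Generalized Akaike information criterion
#'
#' `deviance + k * df`: `k = 2` is the AIC, `k = log(n)` the BIC.
#'
#' @param global_deviance -2 maximized log-likelihood.
#' @param df_total total (effective) degrees of freedom.
#' @param k penalty per df, >= 0.
#' @return Numeric.
#' @export
gaic <- function(global_deviance, df_total, k) {
  if (any(df_total < 0) || any(k < 0)) {
    stop("'df_total' and 'k' must be non-negative", call. = FALSE)
  }
  global_deviance + k * df_total
}

#' Goodness-of-fit report for a centile model
#'
#' @param model a fitted [fit_centile_model()] object.
#' @param records the data to evaluate coverage on (typically the training
#'   records).
#' @param k extra GAIC penalty to report (default 3).
#' @return Object of class `"fit_report"`: `global_deviance`, `df_total`,
#'   `aic`, `bic`, `gaic_k`, `k`, `n`, `coverage_3rd` and `coverage_97th`
#'   (percent of records strictly below the fitted 3rd / above the 97th
#'   centile).
#' @export
fit_report <- function(model, records, k = 3) {
  records <- validate_crosssec(records)
  q03 <- suppressWarnings(model_centile(model, records$ga_weeks, 3))
  q97 <- suppressWarnings(model_centile(model, records$ga_weeks, 97))
  structure(list(
    global_deviance = model$global_deviance,
    df_total = model$df_total,
    n = model$n_obs,
    aic = gaic(model$global_deviance, model$df_total, 2),
    bic = gaic(model$global_deviance, model$df_total, log(model$n_obs)),
    gaic_k = gaic(model$global_deviance, model$df_total, k),
    k = k,
    coverage_3rd = 100 * mean(records$value < q03),
    coverage_97th = 100 * mean(records$value > q97)
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("deviance %.2f on df %.2f (n = %d)\n", x$global_deviance,
              x$df_total, x$n))
  cat(sprintf("AIC %.2f | BIC %.2f | GAIC(%g) %.2f\n", x$aic, x$bic, x$k,
              x$gaic_k))
  cat(sprintf("coverage: %.2f%% below 3rd, %.2f%% above 97th\n",
              x$coverage_3rd, x$coverage_97th))
  invisible(x)
}

#' @export
print.centile_model <- function(x, ...) {
  cat(sprintf("Centile model, family %s, n = %d\n", x$family, x$n_obs))
  for (p in names(x$curves)) {
    cv <- x$curves[[p]]
    desc <- switch(cv$spec$kind,
                   constant = "constant",
                   fp = sprintf("FP(%s)", paste(cv$spec$powers, collapse = ", ")),
                   pspline = sprintf("pspline edf %.1f", cv$edf))
    cat(sprintf("  %-5s %s, link %s\n", p, desc, cv$link))
  }
  print(x$report)
  invisible(x)
}

#' Add-up stepwise selection across model classes
#'
#' Candidates are grouped by the number of distribution parameters of their
#' family (2-, 3- and 4-parameter classes). The best model in each class by
#' GAIC(k) is found; starting from the simplest class, a more complex class
#' is adopted only if its best GAIC improves on the incumbent by more than
#' `margin` (default 0, i.e. strict improvement). The full ranked table is
#' returned so that non-statistical criteria can override the choice.
#'
#' @param records cross-sectional records.
#' @param candidates list of candidates, each a list with elements `family`,
#'   `curve_specs` (and optionally `label`).
#' @param k GAIC penalty per df (default 2 = AIC).
#' @param margin required GAIC improvement to move up a class.
#' @param ... passed to [fit_centile_model()].
#' @return List with `table` (ranked data frame), `chosen` (the selected
#'   fitted model) and `fits` (all fitted models, by label).
#' @export
stepwise_class_selection <- function(records, candidates, k = 2, margin = 0,
                                     ...) {
  labels <- vapply(seq_along(candidates), function(i) {
    if (!is.null(candidates[[i]]$label)) candidates[[i]]$label
    else sprintf("M%d_%s", i, candidates[[i]]$family)
  }, character(1))
  fits <- vector("list", length(candidates))
  names(fits) <- labels
  rows <- list()
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fit <- tryCatch(
      fit_centile_model(records, cand$family,
                        cand$curve_specs %||% list(), ...),
      error = function(e) {
        warning(sprintf("candidate %s failed: %s", labels[i], conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    fits[[i]] <- fit
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      label = labels[i], family = cand$family,
      n_param = family_npar(cand$family),
      deviance = fit$global_deviance, df = fit$df_total,
      gaic = gaic(fit$global_deviance, fit$df_total, k),
      aic = fit$report$aic, bic = fit$report$bic,
      coverage_3rd = fit$report$coverage_3rd,
      coverage_97th = fit$report$coverage_97th,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no candidate model could be fitted", call. = FALSE)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$gaic), , drop = FALSE]
  rownames(tab) <- NULL
  classes <- sort(unique(tab$n_param))
  chosen_label <- NULL
  chosen_gaic <- Inf
  for (cl in classes) {
    sub <- tab[tab$n_param == cl, , drop = FALSE]
    if (!nrow(sub)) { warning(sprintf("empty %d-parameter class", cl)); next }
    best <- sub[which.min(sub$gaic), ]
    ## promote only on strict improvement beyond the margin
    if (is.null(chosen_label) || best$gaic < chosen_gaic - margin) {
      chosen_label <- best$label
      chosen_gaic <- best$gaic
    }
  }
  list(table = tab, chosen = fits[[chosen_label]], fits = fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
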