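#' Design facts of the emulated studies
#'
#' The cohort design quantities that the synthetic generators reproduce: a
#' newborn cross-sectional study (per-completed-week delivery counts by sex,
#' with heaping at 39-40 weeks and very few deliveries before 34 weeks) and
#' a longitudinal fetal ultrasound study (4233 women, visits every 5 (+/- 1)
#' weeks from 14 weeks, one to six visits each, triplicate measurements per
#' visit with 117 missing replicates overall, 20 030 visits in total; 59 137
#' women screened of whom 20 486 met the eligibility criteria).
#'
#' @return A list with components `newborn` (data frame: `week`, `boys`,
#'   `girls`) and `fetal` (list: `n_subjects`, `visit_counts` — women by
#'   exact number of visits 1..6 —, `n_visits`, `replicates_per_visit`,
#'   `missing_replicates`, `screened`, `eligible`).
#' @export
design_facts <- function() {
  list(
    newborn = data.frame(
      week = 33:42,
      boys = c(34L, 48L, 128L, 323L, 857L, 2045L, 3009L, 2568L, 1179L, 206L),
      girls = c(17L, 65L, 114L, 293L, 803L, 1802L, 2869L, 2523L, 1195L, 224L)),
    fetal = list(
      n_subjects = 4233L,
      visit_counts = c(`1` = 39L, `2` = 55L, `3` = 203L, `4` = 810L,
                       `5` = 2724L, `6` = 402L),
      n_visits = 20030L,
      replicates_per_visit = 3L,
      missing_replicates = 117L,
      screened = 59137L,
      eligible = 20486L)
  )
}

#' Configuration for the cross-sectional newborn generator
#'
#' @param n number of newborns to generate.
#' @param sex `"M"` or `"F"`; selects the default week weights.
#' @param ga_weights named numeric vector of probabilities over completed
#'   weeks (names = weeks); default proportional to the per-week delivery
#'   counts of the emulated design ([design_facts()]), i.e. heaped at term.
#' @param family distribution family of the measurement given GA.
#' @param mu,sigma,nu,tau true parameter curves: each a function of exact GA
#'   (or a constant). Defaults describe birthweight in grams with a mean
#'   rising to about 3.4 kg at 40 weeks and an SD growing with GA.
#' @param seed integer seed.
#' @return List of class `"crosssec_config"`.
#' @export
crosssec_config <- function(n = 10397, sex = "M", ga_weights = NULL,
                            family = "NO",
                            mu = function(t) 3400 + 190 * (t - 40) - 4 * (t - 40)^2,
                            sigma = function(t) 400 + 15 * (t - 40),
                            nu = NULL, tau = NULL, seed = 1) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (is.null(ga_weights)) {
    des <- design_facts()$newborn
    counts <- if (identical(sex, "F")) des$girls else des$boys
    ga_weights <- stats::setNames(counts / sum(counts), des$week)
  }
  if (abs(sum(ga_weights) - 1) > 1e-8) {
    stop("'ga_weights' must sum to 1", call. = FALSE)
  }
  family <- match.arg(family, FAMILIES)
  structure(list(n = as.integer(n), sex = sex, ga_weights = ga_weights,
                 family = family,
                 curves = list(mu = mu, sigma = sigma, nu = nu, tau = tau),
                 seed = as.integer(seed)),
            class = "crosssec_config")
}

eval_truth_curve <- function(curve, t) {
  if (is.null(curve)) return(NULL)
  if (is.function(curve)) curve(t) else rep_len(as.numeric(curve), length(t))
}

#' Generate a cross-sectional newborn-style dataset
#'
#' Completed weeks are drawn from the configured (heaped) weight table, the
#' within-week position is uniform, and the measurement is drawn from the
#' configured family at the true parameter curves. The generating truth is
#' returned alongside the records for parameter-recovery tests.
#'
#' @param config a [crosssec_config()].
#' @return List with `records` (data frame `id`, `sex`, `ga_weeks`, `value`)
#'   and `truth` (the config).
#' @export
gen_newborn <- function(config = crosssec_config()) {
  stopifnot(inherits(config, "crosssec_config"))
  set.seed(config$seed)
  weeks <- as.numeric(names(config$ga_weights))
  wk <- weeks[sample.int(length(weeks), config$n, replace = TRUE,
                         prob = config$ga_weights)]
  ga <- wk + stats::runif(config$n)
  params <- Filter(Negate(is.null), lapply(config$curves, eval_truth_curve, t = ga))
  u <- pmin(pmax(stats::runif(config$n), 1e-12), 1 - 1e-12)
  value <- family_quantile(config$family, params, u)
  list(records = data.frame(id = sprintf("N%05d", seq_len(config$n)),
                            sex = config$sex, ga_weeks = ga, value = value,
                            stringsAsFactors = FALSE),
       truth = config)
}

#' Configuration for the longitudinal fetal generator
#'
#' Defaults emulate the longitudinal fetal head circumference design: 4233
#' subjects, first visit in week 14, subsequent visits every 5 (+/- 1,
#' uniform) weeks truncated at 42, number of visits drawn from the observed
#' distribution over 1..6 (93% of women attend at least 4), triplicate
#' measurements per visit with replicates missing completely at random at
#' rate 117/60090. The true mean curve is the published FHC mean equation,
#' and the default variance components were chosen so the implied total SD
#' tracks the published FHC SD equation, making the published standard
#' double as the generator truth.
#'
#' @param n_subjects number of subjects.
#' @param first_visit_ga gestational age of the first visit window (weeks).
#' @param visit_interval mean spacing between visits (weeks).
#' @param visit_jitter half-width of the uniform spacing jitter (weeks).
#' @param max_ga visits beyond this age are dropped.
#' @param visit_probs probability over 1..6 visits per subject.
#' @param fixed_curve true mean: an [fp_spec()] or function of GA.
#' @param var_intercept,var_slope,cov_int_slope subject-level random
#'   intercept/slope covariance (slope on raw GA).
#' @param var_visit visit-level variance (mm^2).
#' @param triplicate_sd within-visit replicate SD (mm).
#' @param missing_rate probability a replicate is missing.
#' @param seed integer seed.
#' @return List of class `"long_config"`.
#' @export
long_config <- function(n_subjects = 4233, first_visit_ga = 14,
                        visit_interval = 5, visit_jitter = 1, max_ga = 42,
                        visit_probs = NULL,
                        fixed_curve = NULL,
                        var_intercept = 47.3, var_slope = 0.2018,
                        cov_int_slope = -2.455, var_visit = 4,
                        triplicate_sd = 3,
                        missing_rate = 117 / 60090, seed = 1) {
  if (is.null(visit_probs)) {
    cnt <- design_facts()$fetal$visit_counts
    visit_probs <- cnt / sum(cnt)
  }
  if (abs(sum(visit_probs) - 1) > 1e-8) {
    stop("'visit_probs' must sum to 1", call. = FALSE)
  }
  if (var_intercept < 0 || var_slope < 0 || var_visit < 0 || triplicate_sd < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  if (var_intercept * var_slope < cov_int_slope^2 - 1e-12) {
    stop("random-effects covariance matrix is not positive semi-definite",
         call. = FALSE)
  }
  if (is.null(fixed_curve)) fixed_curve <- published_fhc_chart()$mean_curve
  structure(list(n_subjects = as.integer(n_subjects),
                 first_visit_ga = first_visit_ga,
                 visit_interval = visit_interval, visit_jitter = visit_jitter,
                 max_ga = max_ga, visit_probs = visit_probs,
                 fixed_curve = fixed_curve,
                 var_intercept = var_intercept, var_slope = var_slope,
                 cov_int_slope = cov_int_slope, var_visit = var_visit,
                 triplicate_sd = triplicate_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "long_config")
}

#' Generate a longitudinal fetal-style triplicate dataset
#'
#' Per subject: the visit count is drawn from the configured distribution;
#' visit ages follow a jittered schedule from the first-visit week, truncated
#' at `max_ga`; a subject-level random intercept and GA-slope are drawn from
#' the configured covariance; each visit value is fixed(ga) + intercept +
#' slope*ga + visit noise, and each of the three replicates adds independent
#' triplicate error. Replicates are masked completely at random at the
#' configured missing rate. Subjects whose schedule yields no in-range visit
#' are redrawn (and counted).
#'
#' @param config a [long_config()].
#' @return List with `records` (data frame `id`, `visit`, `replicate`,
#'   `ga_weeks`, `value`, missing replicates as `NA`), `truth` (the config)
#'   and `n_redrawn`.
#' @export
gen_fetal <- function(config = long_config()) {
  stopifnot(inherits(config, "long_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  Sigma <- matrix(c(config$var_intercept, config$cov_int_slope,
                    config$cov_int_slope, config$var_slope), 2)
  ch <- chol_psd(Sigma)
  re <- matrix(stats::rnorm(2 * n), n) %*% ch # intercept, slope per subject
  mean_fn <- if (is.function(config$fixed_curve)) config$fixed_curve else
    function(t) predict(config$fixed_curve, t)
  rows <- vector("list", n)
  n_redrawn <- 0L
  for (i in seq_len(n)) {
    repeat {
      k <- sample.int(length(config$visit_probs), 1L,
                      prob = config$visit_probs)
      ga <- config$first_visit_ga + stats::runif(1)
      gas <- numeric(0)
      for (v in seq_len(k)) {
        if (v > 1L) {
          ga <- ga + config$visit_interval +
            stats::runif(1, -config$visit_jitter, config$visit_jitter)
        }
        if (ga <= config$max_ga) gas <- c(gas, ga)
      }
      if (length(gas)) break
      n_redrawn <- n_redrawn + 1L
    }
    nv <- length(gas)
    visit_val <- mean_fn(gas) + re[i, 1] + re[i, 2] * gas +
      stats::rnorm(nv, 0, sqrt(config$var_visit))
    vals <- rep(visit_val, each = 3L) +
      stats::rnorm(3L * nv, 0, config$triplicate_sd)
    rows[[i]] <- data.frame(
      id = sprintf("F%05d", i),
      visit = rep(seq_len(nv), each = 3L),
      replicate = rep(1:3, nv),
      ga_weeks = rep(gas, each = 3L),
      value = vals, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  miss <- stats::runif(nrow(records)) < config$missing_rate
  records$value[miss] <- NA_real_
  rownames(records) <- NULL
  list(records = records, truth = config, n_redrawn = n_redrawn)
}

## Cholesky factor tolerant of semi-definite matrices (zero variances)
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}
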