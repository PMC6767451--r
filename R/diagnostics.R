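## Blom plotting positions for a sample of size n
blom_positions <- function(n) ((1:n) - 3 / 8) / (n + 1 / 4)

#' Worm plot data (detrended Q-Q by age group)
#'
#' Observations are split into `n_groups` equal-count gestational-age bins
#' (`n_groups = 1` gives a single worm for the whole range). Within each
#' group the deviations are the ordered Z-scores minus the theoretical
#' normal quantiles at Blom plotting positions; a flat worm near zero
#' indicates adequate fit in that age range. A cubic polynomial is fitted to
#' each worm by least squares to summarize its shape. Groups with fewer than
#' 10 points are merged with a neighbour.
#'
#' @param zscores numeric vector of fitted Z-scores.
#' @param ga gestational ages, same length.
#' @param n_groups number of age groups (default 9).
#' @return Object of class `"worm_data"`: a list with one element per group,
#'   each holding `ga_interval`, `n`, `theoretical`, `deviation` and `cubic`
#'   (coefficients of the least-squares cubic in the theoretical quantile).
#' @export
worm_data <- function(zscores, ga, n_groups = 9) {
  if (length(zscores) != length(ga)) {
    stop("'zscores' and 'ga' must have equal length", call. = FALSE)
  }
  if (n_groups < 1) stop("'n_groups' must be at least 1", call. = FALSE)
  ok <- is.finite(zscores) & is.finite(ga)
  zscores <- zscores[ok]; ga <- ga[ok]
  breaks <- unique(stats::quantile(ga, probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- cut(ga, breaks, include.lowest = TRUE)
  counts <- table(grp)
  ## merge undersized groups with their left neighbour
  while (length(counts) > 1L && any(counts < 10)) {
    i <- which(counts < 10)[1L]
    j <- if (i == 1L) 2L else i - 1L
    breaks <- breaks[-max(i, j)]
    message("merged an age group with fewer than 10 observations")
    grp <- cut(ga, breaks, include.lowest = TRUE)
    counts <- table(grp)
  }
  groups <- lapply(levels(grp), function(lv) {
    z <- sort(zscores[grp == lv])
    n <- length(z)
    theo <- stats::qnorm(blom_positions(n))
    dev <- z - theo
    cubic <- if (n >= 4)
      unname(stats::lm.fit(cbind(1, theo, theo^2, theo^3), dev)$coefficients)
    else rep(NA_real_, 4)
    gs <- ga[grp == lv]
    list(ga_interval = range(gs), n = n, theoretical = theo,
         deviation = dev, cubic = cubic)
  })
  structure(groups, breaks = breaks, class = "worm_data")
}

#' @export
print.worm_data <- function(x, ...) {
  cat(sprintf("Worm plot data: %d age group(s)\n", length(x)))
  for (g in x) {
    cat(sprintf("  GA [%.2f, %.2f], n = %d, mean deviation %+.3f, cubic %+.3f\n",
                g$ga_interval[1], g$ga_interval[2], g$n, mean(g$deviation),
                g$cubic[4]))
  }
  invisible(x)
}

#' Empirical centile coverage
#'
#' For each requested centile, the percent of records in the relevant tail
#' of the fitted centile: strictly below for centiles up to the median,
#' strictly above for centiles beyond it. For a well-fitting model about 3%
#' of the data lie below the 3rd and above the 97th fitted centiles. Exact
#' binomial 95% intervals accompany each observed percentage.
#'
#' @param model_centile_fn function `(ga, centile) -> value`, e.g.
#'   `function(ga, c) model_centile(fit, ga, c)`.
#' @param records data frame with `ga_weeks` and `value`.
#' @param centiles centiles in percent (default `c(3, 97)`).
#' @return Data frame of class `"coverage_table"` with columns `centile`,
#'   `side`, `expected_pct`, `observed_pct`, `count`, `n`, `ci_lower`,
#'   `ci_upper`.
#' @export
coverage <- function(model_centile_fn, records, centiles = c(3, 97)) {
  records <- validate_crosssec(records, require_id = FALSE)
  rows <- lapply(centiles, function(cc) {
    q <- suppressWarnings(model_centile_fn(records$ga_weeks, cc))
    n <- nrow(records)
    if (cc <= 50) {
      cnt <- sum(records$value < q); side <- "below"; expct <- cc
    } else {
      cnt <- sum(records$value > q); side <- "above"; expct <- 100 - cc
    }
    ci <- stats::binom.test(cnt, n)$conf.int
    data.frame(centile = cc, side = side, expected_pct = expct,
               observed_pct = 100 * cnt / n, count = cnt, n = n,
               ci_lower = 100 * ci[1], ci_upper = 100 * ci[2])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(centile = numeric(0), side = character(0),
               expected_pct = numeric(0), observed_pct = numeric(0),
               count = integer(0), n = integer(0),
               ci_lower = numeric(0), ci_upper = numeric(0))
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Normal Q-Q data for Z-scores
#'
#' Ordered Z-scores against theoretical standard-normal quantiles at Blom
#' plotting positions.
#'
#' @param zscores numeric vector, length >= 2.
#' @return Data frame with columns `theoretical` and `empirical`.
#' @export
qq_data <- function(zscores) {
  zscores <- zscores[is.finite(zscores)]
  if (length(zscores) < 2L) stop("need at least 2 Z-scores", call. = FALSE)
  data.frame(theoretical = stats::qnorm(blom_positions(length(zscores))),
             empirical = sort(zscores))
}

#' Residual-versus-age data
#'
#' @param zscores fitted Z-scores (or residuals).
#' @param ga gestational ages.
#' @return Data frame `ga`, `zscore`, ordered by age, for plotting residual
#'   spread against gestational age.
#' @export
residual_age_data <- function(zscores, ga) {
  if (length(zscores) != length(ga)) {
    stop("'zscores' and 'ga' must have equal length", call. = FALSE)
  }
  o <- order(ga)
  data.frame(ga = ga[o], zscore = zscores[o])
}

#' Model comparison table
#'
#' Ranks a set of fit reports (from models fitted to the *same* data) by
#' deviance, AIC, BIC or GAIC. Presentation offsets (such as subtracting a
#' round number from every deviance) are applied at display only.
#'
#' @param reports list of [fit_report()] objects (optionally named).
#' @param criterion `"gaic"`, `"aic"`, `"bic"` or `"deviance"`.
#' @param offset value subtracted from the deviance/AIC/BIC columns for
#'   display (default 0).
#' @return Data frame ranked by the criterion.
#' @export
comparison_table <- function(reports, criterion = c("gaic", "aic", "bic", "deviance"),
                             offset = 0) {
  criterion <- match.arg(criterion)
  ns <- vapply(reports, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1L) {
    stop("fit reports come from different data sets (unequal n)", call. = FALSE)
  }
  labels <- names(reports) %||% paste0("model", seq_along(reports))
  tab <- data.frame(
    model = labels,
    deviance = vapply(reports, `[[`, numeric(1), "global_deviance") - offset,
    df = vapply(reports, `[[`, numeric(1), "df_total"),
    aic = vapply(reports, `[[`, numeric(1), "aic") - offset,
    bic = vapply(reports, `[[`, numeric(1), "bic") - offset,
    gaic = vapply(reports, `[[`, numeric(1), "gaic_k") - offset,
    coverage_3rd = vapply(reports, `[[`, numeric(1), "coverage_3rd"),
    coverage_97th = vapply(reports, `[[`, numeric(1), "coverage_97th"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab[[criterion]]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
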