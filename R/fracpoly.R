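## The standard restricted fractional-polynomial power set.
FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial specification
#'
#' Bundle the degree, power tuple and coefficients of a fitted (or externally
#' supplied) fractional polynomial of a positive covariate, typically
#' gestational age in exact weeks. Power 0 denotes the natural logarithm of
#' the covariate, and a power repeated r times contributes the columns
#' `x^p * log(x)^(0..r-1)`.
#'
#' @param powers numeric vector of powers, each from
#'   `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}`, in non-decreasing order.
#' @param coefficients numeric vector of length `length(powers) + 1`,
#'   intercept first.
#' @param scale_shift optional non-negative offset added to the covariate
#'   before powering (the shift of a shifted transformation); default 0.
#' @return An object of class `"fp_spec"`.
#' @examples
#' sp <- fp_spec(c(0, 2, 2), c(-28.3, 1.7, -0.4, 0.01))
#' predict(sp, 20:40)
#' @export
fp_spec <- function(powers, coefficients, scale_shift = 0) {
  powers <- as.numeric(powers)
  check_fp_powers(powers)
  if (is.unsorted(powers)) {
    stop("'powers' must be non-decreasing (canonical ordering)", call. = FALSE)
  }
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(powers) + 1L) {
    stop("'coefficients' must have length degree + 1 (intercept first)",
         call. = FALSE)
  }
  if (!is.numeric(scale_shift) || length(scale_shift) != 1L || scale_shift < 0) {
    stop("'scale_shift' must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(degree = length(powers), powers = powers,
         coefficients = coefficients, scale_shift = scale_shift),
    class = "fp_spec"
  )
}

check_fp_powers <- function(powers) {
  if (length(powers) < 1L) {
    stop("at least one power is required", call. = FALSE)
  }
  if (!all(powers %in% FP_POWERS)) {
    stop("powers must belong to the restricted set {-2, -1, -0.5, 0, 0.5, 1, 2, 3}",
         call. = FALSE)
  }
  invisible(powers)
}

#' Fractional-polynomial basis matrix
#'
#' Construct the design columns of a fractional polynomial: column j is
#' `x^p_j`, where power 0 denotes `log(x)` and a power repeated r times yields
#' `x^p, x^p*log(x), ..., x^p*log(x)^(r-1)`. The intercept column is *not*
#' included.
#'
#' @param x positive numeric vector (after any shift).
#' @param powers non-decreasing numeric vector of powers from the restricted
#'   set.
#' @param scale_shift non-negative offset added to `x` before powering.
#' @return Numeric matrix with `length(powers)` columns.
#' @examples
#' fp_basis(exp(1), c(0, 2, 2)) # 1, e^2, e^2
#' @export
fp_basis <- function(x, powers, scale_shift = 0) {
  powers <- as.numeric(powers)
  check_fp_powers(powers)
  if (is.unsorted(powers)) {
    stop("'powers' must be non-decreasing (canonical ordering)", call. = FALSE)
  }
  x <- as.numeric(x) + scale_shift
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("covariate values must be positive (after 'scale_shift')", call. = FALSE)
  }
  lx <- log(x)
  m <- length(powers)
  out <- matrix(NA_real_, length(x), m)
  rep_count <- 0L
  for (j in seq_len(m)) {
    p <- powers[j]
    rep_count <- if (j > 1L && p == powers[j - 1L]) rep_count + 1L else 0L
    base <- if (p == 0) lx else x^p
    ## repeated power: multiply the base column by log(x)^rep_count
    out[, j] <- base * lx^rep_count
  }
  colnames(out) <- fp_term_labels(powers)
  out
}

fp_term_labels <- function(powers) {
  m <- length(powers)
  labs <- character(m)
  rep_count <- 0L
  for (j in seq_len(m)) {
    p <- powers[j]
    rep_count <- if (j > 1L && p == powers[j - 1L]) rep_count + 1L else 0L
    base <- if (p == 0) "log(x)" else sprintf("x^%g", p)
    labs[j] <- if (rep_count == 0L) base else
      sprintf("%s.log(x)^%d", base, rep_count)
  }
  labs
}

#' Enumerate canonical fractional-polynomial power tuples
#'
#' All non-decreasing tuples of the given degree over the restricted power
#' set, repeats allowed: 8 models for degree 1, 36 for degree 2, 120 for
#' degree 3.
#'
#' @param degree integer, 1, 2 or 3.
#' @return List of numeric power tuples in lexicographic order.
#' @export
enumerate_fp_models <- function(degree) {
  if (length(degree) != 1L || !degree %in% 1:3) {
    stop("'degree' must be 1, 2 or 3", call. = FALSE)
  }
  idx <- combn_with_repetition(length(FP_POWERS), degree)
  lapply(seq_len(ncol(idx)), function(j) FP_POWERS[idx[, j]])
}

## non-decreasing index tuples 1..n of length k, lexicographic order
combn_with_repetition <- function(n, k) {
  if (k == 1L) return(matrix(seq_len(n), 1L))
  sub <- NULL
  cols <- list()
  for (first in seq_len(n)) {
    rest <- combn_with_repetition(n - first + 1L, k - 1L) + first - 1L
    cols[[first]] <- rbind(first, rest)
  }
  do.call(cbind, cols)
}

#' Fit a fractional polynomial by exhaustive best-power search
#'
#' Ordinary (or weighted) least squares over every canonical power tuple of
#' the requested degree; the tuple with the smallest residual sum of squares
#' wins, ties broken in favour of the lexicographically smallest tuple.
#' Rank-deficient candidate bases are skipped with a warning.
#'
#' @param x positive numeric covariate (gestational age in exact weeks).
#' @param y numeric response.
#' @param weights optional non-negative case weights.
#' @param degree FP degree (number of powers), 1, 2 or 3.
#' @param powers optional fixed power tuple; when supplied the search is
#'   skipped and only these powers are fitted.
#' @param scale_shift non-negative covariate offset.
#' @return An object of class `"fp_fit"` (which also inherits `"fp_spec"`)
#'   with elements `powers`, `coefficients`, `rss`, `deviance`
#'   (Gaussian -2 log-likelihood), `n`, `fitted`, `residuals`.
#' @examples
#' x <- seq(33, 42, length.out = 200)
#' y <- 1 + 2 * log(x)
#' fit_fp(x, y, degree = 1)$powers # 0
#' @export
fit_fp <- function(x, y, weights = NULL, degree = 2, powers = NULL,
                   scale_shift = 0) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != length(y) || any(weights < 0)) {
      stop("'weights' must be non-negative and match the data length",
           call. = FALSE)
    }
  }
  candidates <- if (is.null(powers)) enumerate_fp_models(degree) else
    list(sort(as.numeric(powers)))
  degree <- length(candidates[[1L]])
  if (length(y) < degree + 2L) {
    stop("need at least degree + 2 observations", call. = FALSE)
  }
  best <- NULL
  skipped <- character(0)
  for (p in candidates) {
    B <- cbind(1, fp_basis(x, p, scale_shift))
    fit <- tryCatch(
      if (is.null(weights)) stats::lm.fit(B, y) else
        stats::lm.wfit(B, y, weights),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$rank < ncol(B) ||
        any(!is.finite(fit$coefficients))) {
      skipped <- c(skipped, paste(p, collapse = ","))
      next
    }
    w <- if (is.null(weights)) rep(1, length(y)) else weights
    rss <- sum(w * fit$residuals^2)
    ## strict improvement keeps the lexicographically first tuple on ties
    if (is.null(best) || rss < best$rss * (1 - 1e-10)) {
      best <- list(powers = p, coefficients = unname(fit$coefficients),
                   rss = rss, fitted = as.numeric(B %*% fit$coefficients),
                   residuals = y - as.numeric(B %*% fit$coefficients))
    }
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d rank-deficient candidate power tuple(s): %s",
                    length(skipped), paste(skipped, collapse = "; ")),
            call. = FALSE)
  }
  if (is.null(best)) stop("all candidate fractional polynomials failed to fit",
                          call. = FALSE)
  n <- length(y)
  spec <- fp_spec(best$powers, best$coefficients, scale_shift)
  spec$rss <- best$rss
  spec$n <- n
  ## Gaussian profile -2 log-likelihood
  spec$deviance <- n * (log(2 * pi * best$rss / n) + 1)
  spec$fitted <- best$fitted
  spec$residuals <- best$residuals
  class(spec) <- c("fp_fit", "fp_spec")
  spec
}

#' Evaluate a fractional polynomial
#'
#' @param object an [fp_spec()] or [fit_fp()] object.
#' @param newdata positive numeric vector of covariate values.
#' @param ... unused.
#' @return Numeric vector of fitted values.
#' @export
predict.fp_spec <- function(object, newdata, ...) {
  B <- cbind(1, fp_basis(newdata, object$powers, object$scale_shift))
  as.numeric(B %*% object$coefficients)
}

#' @export
print.fp_spec <- function(x, ...) {
  cat(sprintf("Fractional polynomial FP%d, powers (%s)\n", x$degree,
              paste(x$powers, collapse = ", ")))
  co <- x$coefficients
  names(co) <- c("(Intercept)", fp_term_labels(x$powers))
  print(co)
  if (!is.null(x$rss)) {
    cat(sprintf("RSS %.6g on n = %d, deviance %.6g\n", x$rss, x$n, x$deviance))
  }
  invisible(x)
}
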