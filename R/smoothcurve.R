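#' Specify a smooth parameter curve
#'
#' Describes how one distribution parameter (mu, sigma, nu or tau) varies
#' with gestational age inside a centile model: a constant, a fractional
#' polynomial with fixed powers, or a penalized cubic B-spline smoothed to a
#' target effective degrees of freedom (edf). As usual, edf = 1 is a
#' constant, edf = 2 a straight line and edf = 3 about a quadratic.
#'
#' @param kind `"constant"`, `"fp"` or `"pspline"`.
#' @param powers FP power tuple (required for `kind = "fp"`).
#' @param edf target effective degrees of freedom (required for
#'   `kind = "pspline"`; must exceed 2 and may be fractional, e.g. 3.6).
#' @param n_basis number of B-spline basis functions for `"pspline"`
#'   (default grows with `edf`).
#' @return Object of class `"curve_spec"`.
#' @examples
#' curve_spec("pspline", edf = 3.6)
#' curve_spec("fp", powers = c(2, 2))
#' @export
curve_spec <- function(kind = c("constant", "fp", "pspline"), powers = NULL,
                       edf = NULL, n_basis = NULL) {
  kind <- match.arg(kind)
  if (kind == "fp") {
    if (is.null(powers)) stop("'powers' required for an fp curve", call. = FALSE)
    powers <- sort(as.numeric(powers))
    check_fp_powers(powers)
    edf <- length(powers) + 1
  } else if (kind == "pspline") {
    if (is.null(edf) || edf <= 2) {
      stop("a pspline curve needs a target 'edf' > 2", call. = FALSE)
    }
    if (is.null(n_basis)) n_basis <- max(8L, ceiling(edf) + 3L)
    if (n_basis < edf + 1) stop("'n_basis' must exceed the target edf", call. = FALSE)
  } else {
    edf <- 1
  }
  structure(list(kind = kind, powers = powers, edf = edf, n_basis = n_basis),
            class = "curve_spec")
}

## cubic B-spline design with equally spaced interior knots; x clamped to the
## boundary so that chart grids slightly outside the data do not error
## (constant extrapolation of the basis).
pspline_knots <- function(ga_range, n_basis) {
  b <- ga_range + c(-1e-8, 1e-8)
  n_int <- n_basis - 4L
  interior <- if (n_int > 0) seq(b[1], b[2], length.out = n_int + 2L)[-c(1, n_int + 2L)] else numeric(0)
  c(rep(b[1], 4L), interior, rep(b[2], 4L))
}

eval_pspline_basis <- function(x, knots) {
  b <- range(knots)
  x <- pmin(pmax(x, b[1] + 1e-10), b[2] - 1e-10)
  splines::splineDesign(knots, x, ord = 4L)
}

## second-order penalty on the spline coefficients, built from second
## divided differences at the Greville abscissae so that the penalty null
## space is exactly the linear functions (edf -> 2 gives a straight line
## even with repeated boundary knots)
diff_penalty <- function(knots) {
  k <- length(knots) - 4L
  xi <- (knots[2:(k + 1)] + knots[3:(k + 2)] + knots[4:(k + 3)]) / 3
  D <- matrix(0, k - 2L, k)
  for (i in seq_len(k - 2L)) {
    h1 <- xi[i + 1] - xi[i]
    h2 <- xi[i + 2] - xi[i + 1]
    D[i, i:(i + 2)] <- c(1 / h1, -(1 / h1 + 1 / h2), 1 / h2) * 2 /
      (xi[i + 2] - xi[i])
  }
  crossprod(D)
}

## effective degrees of freedom of the penalized smoother at penalty lambda
pspline_edf <- function(BtB, P, lambda) {
  sum(diag(solve(BtB + lambda * P, BtB)))
}

## solve lambda so that the smoother's edf equals the target (continuous in
## log-lambda, so fractional targets such as 3.6 are honored exactly)
solve_lambda <- function(BtB, P, target_edf) {
  k <- ncol(BtB)
  if (target_edf >= k - 1e-8) return(0)
  f <- function(loglam) pspline_edf(BtB, P, exp(loglam)) - target_edf
  lo <- -12; hi <- 20
  while (f(hi) > 0 && hi < 40) hi <- hi + 5
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root |> exp()
}

## realized basis for one curve on the observed GA values
build_curve <- function(spec, ga, ga_range = range(ga)) {
  out <- list(spec = spec, ga_range = ga_range)
  if (spec$kind == "constant") {
    out$B <- matrix(1, length(ga), 1L)
    out$P <- matrix(0, 1L, 1L)
    out$lambda <- 0
    out$edf <- 1
  } else if (spec$kind == "fp") {
    out$B <- cbind(1, fp_basis(ga, spec$powers))
    k <- ncol(out$B)
    out$P <- matrix(0, k, k)
    out$lambda <- 0
    out$edf <- k
  } else {
    out$knots <- pspline_knots(ga_range, spec$n_basis)
    out$B <- eval_pspline_basis(ga, out$knots)
    out$P <- diff_penalty(out$knots)
    BtB <- crossprod(out$B)
    out$lambda <- solve_lambda(BtB + diag(1e-10, ncol(BtB)), out$P, spec$edf)
    out$edf <- spec$edf
  }
  out
}

## basis at new GA values
curve_basis_at <- function(curve, ga) {
  switch(curve$spec$kind,
         constant = matrix(1, length(ga), 1L),
         fp = cbind(1, fp_basis(ga, curve$spec$powers)),
         pspline = eval_pspline_basis(ga, curve$knots))
}
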