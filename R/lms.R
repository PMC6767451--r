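#' LMS triple
#'
#' The three age-specific quantities of the LMS method at one age: the
#' Box-Cox power `L`, the median `M` and the coefficient of variation `S`.
#'
#' @param L Box-Cox power (real).
#' @param M median, > 0.
#' @param S coefficient of variation, > 0.
#' @return Object of class `"lms_triple"`.
#' @export
lms_triple <- function(L, M, S) {
  if (any(M <= 0)) stop("'M' (median) must be positive", call. = FALSE)
  if (any(S <= 0)) stop("'S' (coefficient of variation) must be positive",
                        call. = FALSE)
  structure(list(L = as.numeric(L), M = as.numeric(M), S = as.numeric(S)),
            class = "lms_triple")
}

LMS_L_TOL <- 1e-8 # |L| below this uses the log-form (L = 0) branch

#' Centile value from an LMS triple
#'
#' `M * (1 + L*S*z)^(1/L)` for `L != 0` and `M * exp(S*z)` for `L = 0`, with
#' `z` the standard-normal quantile of the centile. The two branches are
#' continuous across `|L| < 1e-8`.
#'
#' @param triple an [lms_triple()].
#' @param centile centile(s) in percent, strictly within (0, 100).
#' @return Measurement value(s).
#' @examples
#' lms_centile(lms_triple(0, 100, 0.1), 97) # 100 * exp(0.1 * 1.8808)
#' @export
lms_centile <- function(triple, centile) {
  stopifnot(inherits(triple, "lms_triple"))
  if (any(centile <= 0 | centile >= 100)) {
    stop("'centile' must be strictly between 0 and 100", call. = FALSE)
  }
  z <- stats::qnorm(centile / 100)
  n <- max(length(z), length(triple$L), length(triple$M), length(triple$S))
  z <- rep_len(z, n)
  L <- rep_len(triple$L, n); M <- rep_len(triple$M, n)
  S <- rep_len(triple$S, n)
  arg <- 1 + L * S * z
  bad <- abs(L) >= LMS_L_TOL & arg <= 0
  if (any(bad)) {
    stop(sprintf("centile(s) %s not defined: 1 + L*S*z <= 0",
                 paste(unique(centile[rep_len(bad, length(centile))]),
                       collapse = ", ")), call. = FALSE)
  }
  ifelse(abs(L) < LMS_L_TOL, M * exp(S * z), M * arg^(1 / L))
}

#' SD score (SDS) from an LMS triple
#'
#' `((y/M)^L - 1) / (L*S)` for `L != 0` and `log(y/M) / S` for `L = 0`; the
#' exact inverse of [lms_centile()].
#'
#' @inheritParams lms_centile
#' @param y positive measurement value(s).
#' @return Z-score(s).
#' @export
lms_sds <- function(y, triple) {
  stopifnot(inherits(triple, "lms_triple"))
  if (any(y <= 0)) stop("'y' must be positive", call. = FALSE)
  n <- max(length(y), length(triple$L), length(triple$M), length(triple$S))
  y <- rep_len(y, n)
  L <- rep_len(triple$L, n); M <- rep_len(triple$M, n)
  S <- rep_len(triple$S, n)
  ifelse(abs(L) < LMS_L_TOL,
         log(y / M) / S,
         ((y / M)^L - 1) / (L * S))
}
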