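## Shared fixture builders (everything generated in code; no stored data).

## cross-sectional records from a normal model with linear mean/SD in GA
sim_normal_crosssec <- function(n, seed, ga_lo = 33, ga_hi = 42,
                                mean_fn = function(t) 1000 + 60 * t,
                                sd_fn = function(t) 30 + 5 * (t - 33)) {
  set.seed(seed)
  ga <- stats::runif(n, ga_lo, ga_hi)
  data.frame(ga_weeks = ga,
             value = stats::rnorm(n, mean_fn(ga), sd_fn(ga)))
}

## cross-sectional records drawn from an arbitrary family via inverse CDF
sim_family_crosssec <- function(n, seed, family, param_fn,
                                ga_lo = 14, ga_hi = 42) {
  set.seed(seed)
  ga <- stats::runif(n, ga_lo, ga_hi)
  u <- pmin(pmax(stats::runif(n), 1e-12), 1 - 1e-12)
  data.frame(ga_weeks = ga,
             value = family_quantile(family, param_fn(ga), u))
}

## tiny longitudinal toy set with known triplicates
toy_longitudinal <- function() {
  data.frame(
    id = rep(c("a", "b"), each = 6),
    visit = rep(rep(1:2, each = 3), 2),
    replicate = rep(1:3, 4),
    ga_weeks = rep(c(15, 20, 15.5, 20.5), each = 3),
    value = c(100, 102, 104, 150, 151, 152,
              101, 103, 105, 149, 151, 153),
    stringsAsFactors = FALSE)
}
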