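test_that("gaic matches its definition and aic/bic reconcile exactly", {
  expect_equal(gaic(100, 5, 2), 110)
  expect_equal(gaic(100, 5, 0), 100)
  expect_equal(gaic(50, 1, 10), 60) # k = log(n) with n = e^10
  expect_error(gaic(10, -1, 2), "non-negative")

  d <- sim_normal_crosssec(600, seed = 12)
  m <- fit_centile_model(d, "NO", list(mu = curve_spec("fp", powers = 1)))
  expect_equal(m$report$aic, gaic(m$global_deviance, m$df_total, 2))
  expect_equal(m$report$bic, gaic(m$global_deviance, m$df_total, log(m$n_obs)))
})

test_that("the NO-family model agrees with the mean-SD method", {
  ## near-noiseless linear data: both routes must find the same mean curve
  set.seed(13)
  ga <- runif(800, 33, 42)
  d <- data.frame(ga_weeks = ga, value = 1000 + 60 * ga + rnorm(800, 0, 0.001))
  msd <- fit_mean_sd(d, mean_degree = 1)
  cm <- fit_centile_model(d, "NO", list(mu = curve_spec("fp", powers = 1),
                                        sigma = curve_spec("constant")))
  g <- seq(34, 41, by = 1)
  expect_equal(model_params(cm, g)$mu, predict(msd$mean_curve, g),
               tolerance = 1e-3)
})

test_that("BCCG parameter curves are recovered from simulated data", {
  d <- sim_family_crosssec(5000, seed = 5, "BCCG",
                           function(t) list(mu = 10 + t, sigma = 0.1, nu = 1))
  m <- fit_centile_model(d, "BCCG",
                         list(mu = curve_spec("fp", powers = 1),
                              sigma = curve_spec("constant"),
                              nu = curve_spec("constant")))
  p <- model_params(m, c(20, 40))
  expect_equal(p$mu, c(30, 50), tolerance = 0.02)
  expect_equal(p$sigma[1], 0.1, tolerance = 0.1)
  expect_equal(p$nu[1], 1, tolerance = 0.35)
  ## SDS of the training sample is close to N(0,1)
  z <- model_sds(m, d$ga_weeks, d$value)
  expect_equal(sd(z), 1, tolerance = 0.03)
  expect_equal(mean(z), 0, tolerance = 0.05)
})

test_that("a pspline at edf 2 fits a straight line", {
  set.seed(14)
  ga <- runif(500, 14, 42)
  d <- data.frame(ga_weeks = ga, value = 50 + 3 * ga + rnorm(500, 0, 2))
  m <- fit_centile_model(d, "NO",
                         list(mu = curve_spec("pspline", edf = 2.0001)))
  g <- seq(15, 41, by = 0.5)
  mu <- model_params(m, g)$mu
  curvature <- diff(diff(mu)) / diff(g)[1]^2
  expect_lt(max(abs(curvature)), 0.02) # straight to within noise
  expect_equal(unname(coef(lm(mu ~ g))[2]), 3, tolerance = 0.1)
})

test_that("increasing edf never increases the global deviance", {
  d <- sim_normal_crosssec(1200, seed = 15, ga_lo = 14, ga_hi = 42,
                           mean_fn = function(t) 100 + 5 * t - 0.04 * t^2,
                           sd_fn = function(t) 5 + 0.1 * t)
  m3 <- fit_centile_model(d, "NO", list(mu = curve_spec("pspline", edf = 3)))
  m5 <- fit_centile_model(d, "NO", list(mu = curve_spec("pspline", edf = 5)))
  expect_lte(m5$global_deviance, m3$global_deviance + 1e-6)
  expect_equal(m5$df_total, m3$df_total + 2, tolerance = 1e-6)
})

test_that("training-sample coverage is near nominal at 3/50/97", {
  d <- sim_normal_crosssec(4000, seed = 16)
  m <- fit_centile_model(d, "NO", list(mu = curve_spec("fp", powers = 1),
                                       sigma = curve_spec("fp", powers = 1)))
  expect_equal(m$report$coverage_3rd, 3, tolerance = 0.8)
  expect_equal(m$report$coverage_97th, 3, tolerance = 0.8)
  q50 <- model_centile(m, d$ga_weeks, 50)
  expect_equal(100 * mean(d$value < q50), 50, tolerance = 2)
})

test_that("stepwise selection prefers the right class", {
  ## skewed truth: the three-parameter class must beat the normal
  d <- sim_family_crosssec(1500, seed = 9, "BCCG", ga_lo = 33, ga_hi = 42,
                           function(t) list(mu = 3000 + 100 * (t - 38),
                                            sigma = 0.12, nu = -1.5))
  cand <- list(
    list(family = "NO", label = "NO",
         curve_specs = list(mu = curve_spec("fp", powers = 1),
                            sigma = curve_spec("constant"))),
    list(family = "BCCG", label = "BCCG",
         curve_specs = list(mu = curve_spec("fp", powers = 1),
                            sigma = curve_spec("constant"),
                            nu = curve_spec("constant"))),
    list(family = "BCT", label = "BCT",
         curve_specs = list(mu = curve_spec("fp", powers = 1),
                            sigma = curve_spec("constant"),
                            nu = curve_spec("constant"),
                            tau = curve_spec("constant"))))
  sel <- stepwise_class_selection(d, cand)
  expect_equal(family_npar(sel$chosen$family), 3L)
  expect_true(all(c("gaic", "deviance", "df") %in% names(sel$table)))

  ## normal truth: the simple class is retained over the 4-parameter BCT
  set.seed(17)
  d2 <- data.frame(ga_weeks = d$ga_weeks,
                   value = rnorm(1500, 3000 + 100 * (d$ga_weeks - 38), 300))
  sel2 <- stepwise_class_selection(d2, cand[c(1, 3)])
  expect_equal(sel2$chosen$family, "NO")
})

test_that("identical-deviance candidates keep the simplest class", {
  reports <- list(
    a = structure(list(global_deviance = 100, df_total = 3, n = 50,
                       aic = 106, bic = 111.7, gaic_k = 109, k = 3,
                       coverage_3rd = 3, coverage_97th = 3),
                  class = "fit_report"),
    b = structure(list(global_deviance = 100, df_total = 5, n = 50,
                       aic = 110, bic = 119.6, gaic_k = 115, k = 3,
                       coverage_3rd = 3, coverage_97th = 3),
                  class = "fit_report"))
  tab <- comparison_table(reports, criterion = "aic")
  expect_equal(tab$model[1], "a")
})
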