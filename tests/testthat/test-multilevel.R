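test_that("collapse_triplicates supports mean, median and random", {
  toy <- toy_longitudinal()
  m <- collapse_triplicates(toy, "mean")
  expect_equal(nrow(m), 4L)
  expect_equal(m$value[m$id == "a" & m$visit == 1], 102)
  md <- collapse_triplicates(toy, "median")
  expect_equal(md$value[md$id == "a" & md$visit == 1], 102)
  r1 <- collapse_triplicates(toy, "random", seed = 1)
  r2 <- collapse_triplicates(toy, "random", seed = 1)
  expect_identical(r1$value, r2$value)
  expect_error(collapse_triplicates(toy, "random"), "seed")
})

test_that("missing replicates are averaged over and empty visits dropped", {
  toy <- toy_longitudinal()
  toy$value[toy$id == "a" & toy$visit == 1 & toy$replicate == 3] <- NA
  toy$value[toy$id == "b" & toy$visit == 2] <- NA
  expect_message(m <- collapse_triplicates(toy), "dropped 1 visit")
  expect_equal(nrow(m), 3L)
  expect_equal(m$value[m$id == "a" & m$visit == 1], 101) # mean(100, 102)
  expect_equal(m$n_replicates[m$id == "a" & m$visit == 1], 2L)
  ## row accounting: visits x 3 - missing = observed measurements
  sim <- gen_fetal(long_config(n_subjects = 100, seed = 2,
                               missing_rate = 0.02))
  n_visits <- nrow(unique(sim$records[c("id", "visit")]))
  expect_equal(nrow(sim$records), 3L * n_visits)
  expect_equal(sum(!is.na(sim$records$value)),
               3L * n_visits - sum(is.na(sim$records$value)))
  expect_equal(nrow(collapse_triplicates(sim$records)), n_visits)
})

test_that("ri2 recovers intercept and residual variances", {
  sim <- gen_fetal(long_config(n_subjects = 500, seed = 23,
                               var_intercept = 25, var_slope = 0,
                               cov_int_slope = 0, var_visit = 4,
                               triplicate_sd = 0))
  col <- collapse_triplicates(sim$records)
  f <- fit_multilevel(col, "ri2")
  expect_equal(f$var_intercept, 25, tolerance = 0.2 * 25)
  expect_equal(f$var_residual, 4, tolerance = 0.15 * 4)
  ## superfluous random slope stays near the zero boundary
  fs <- fit_multilevel(col, "ris2")
  expect_lt(fs$var_slope, 0.02)
  expect_equal(fs$var_intercept, 25, tolerance = 0.25 * 25)
})

test_that("ris2 is nested in ri2: deviance never increases", {
  sim <- gen_fetal(long_config(n_subjects = 300, seed = 24))
  col <- collapse_triplicates(sim$records)
  f1 <- fit_multilevel(col, "ri2")
  f2 <- fit_multilevel(col, "ris2")
  expect_lte(f2$deviance, f1$deviance + 1e-6)
})

test_that("identical deterministic subjects give zero variances and the fixed FP", {
  ga <- rep(seq(15, 40, by = 5), 30)
  id <- rep(sprintf("s%02d", 1:30), each = 6)
  truth <- fp_spec(c(2, 2), c(-28.2849, 1.69267, -0.397485))
  d <- data.frame(id = id, visit = rep(1:6, 30), ga_weeks = ga,
                  value = predict(truth, ga))
  f <- fit_multilevel(d, "ri2")
  expect_lt(f$var_intercept, 1e-4)
  expect_lt(f$var_residual, 1e-4)
  expect_equal(f$fixed$coefficients, truth$coefficients, tolerance = 1e-4)
})

test_that("the marginal SD curve reflects the variance components", {
  fake <- structure(list(var_intercept = 0, var_slope = 0, cov_int_slope = 0,
                         var_visit_level = 0, var_residual = 4,
                         ga_center = 0, ga_range = c(14, 42)),
                    class = "multilevel_fit")
  sd_curve <- marginal_sd_curve(fake, sd_degree = 1)
  expect_equal(predict(sd_curve, c(15, 28, 41)), rep(2, 3), tolerance = 1e-8)

  slope <- structure(list(var_intercept = 9, var_slope = 0.04,
                          cov_int_slope = 0, var_visit_level = 0,
                          var_residual = 0, ga_center = 0,
                          ga_range = c(14, 42)),
                     class = "multilevel_fit")
  sdc <- marginal_sd_curve(slope, sd_degree = 3)
  g <- seq(15, 41, by = 2)
  expect_true(all(diff(predict(sdc, g)) > 0)) # grows with age
  expect_equal(predict(sdc, g), sqrt(9 + 0.04 * g^2), tolerance = 0.02)
})

test_that("an exactly-FP3 SD function is reproduced by FP3 smoothing", {
  sd_true <- fp_spec(c(3, 3, 3), c(1.98735, 0.0136772, -0.00726264, 0.000976253))
  g <- seq(14, 42, length.out = 101)
  refit <- fit_fp(g, predict(sd_true, g), degree = 3)
  expect_equal(predict(refit, g), predict(sd_true, g), tolerance = 1e-6)
  expect_equal(refit$powers, c(3, 3, 3))
})

test_that("published FHC equations evaluate to the printed arithmetic", {
  ## frozen from direct arithmetic on the printed coefficients
  mean40 <- -28.2849 + 1.69267 * 1600 - 0.397485 * 1600 * log(40)
  sd40 <- 1.98735 + 0.0136772 * 64000 - 0.00726264 * 64000 * log(40) +
    0.000976253 * 64000 * log(40)^2
  expect_equal(published_fhc(40, 50), mean40, tolerance = 1e-10)
  expect_equal(round(mean40, 1), 333.9)
  expect_equal(round(sd40, 1), 12.9)
  expect_equal(published_fhc(40, 97) - mean40, qnorm(0.97) * sd40,
               tolerance = 1e-10)
  ## z-score inverse pair
  expect_equal(published_fhc_zscore(40, published_fhc(40, 50)), 0,
               tolerance = 1e-12)
  ## positive SD and non-crossing centiles across the whole range
  g <- seq(14, 42, by = 0.25)
  expect_true(all(predict(published_fhc_chart()$sd_curve, g) > 0))
  tab <- chart_table(published_fhc_chart(), c(3, 10, 50, 90, 97), g)
  expect_s3_class(tab, "chart_table")
  expect_warning(published_fhc(43, 50), "extrapolated")
})

test_that("centile coverage of a fitted three-level model is near 3 percent", {
  sim <- gen_fetal(long_config(n_subjects = 400, seed = 26))
  f <- fit_multilevel(sim$records, "ris3")
  chart <- multilevel_chart(f)
  obs <- sim$records[!is.na(sim$records$value), ]
  cov <- coverage(function(ga, cc) multilevel_centile(chart, ga, cc),
                  data.frame(ga_weeks = obs$ga_weeks, value = obs$value))
  expect_equal(cov$observed_pct[cov$centile == 3], 3, tolerance = 1)
  expect_equal(cov$observed_pct[cov$centile == 97], 3, tolerance = 1)
})
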