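test_that("worm deviations vanish for perfectly normal scores", {
  n <- 400
  ## scores placed exactly at the Blom-position normal quantiles
  z <- qnorm(((1:n) - 3 / 8) / (n + 1 / 4))
  ga <- seq(14, 42, length.out = n)
  w <- worm_data(z, ga, n_groups = 1)
  expect_length(w, 1L)
  expect_lt(max(abs(w[[1]]$deviation)), 0.05)
})

test_that("a location shift moves every worm up by the shift", {
  set.seed(41)
  z <- rnorm(2000) + 0.5
  ga <- runif(2000, 14, 42)
  w <- worm_data(z, ga, n_groups = 4)
  for (g in w) expect_lt(abs(mean(g$deviation) - 0.5), 0.25)
  ## pooled over groups the offset matches the shift closely
  expect_equal(mean(unlist(lapply(w, `[[`, "deviation"))), 0.5,
               tolerance = 0.05)
})

test_that("heavy tails produce an S-shaped worm with positive cubic term", {
  set.seed(42)
  z <- rt(8000, df = 5) / sqrt(5 / 3) # standardized t5
  ga <- runif(8000, 14, 42)
  w <- worm_data(z, ga, n_groups = 1)
  expect_gt(w[[1]]$cubic[4], 0)
})

test_that("small age groups are merged with a neighbour", {
  set.seed(40)
  z <- rnorm(25)
  ga <- runif(25, 14, 42)
  ## three requested bins of ~8 observations collapse until all are >= 10
  expect_message(w <- worm_data(z, ga, n_groups = 3), "merged")
  expect_true(all(vapply(w, function(g) g$n, 1) >= 10))
  expect_equal(sum(vapply(w, function(g) g$n, 1)), 25)
})

test_that("coverage counts tails correctly", {
  d <- sim_normal_crosssec(300, seed = 43)
  m <- fit_mean_sd(d)
  fn <- function(ga, cc) normal_centile(m, ga, cc)
  ## values exactly at the median: nothing below the 3rd or above the 97th
  at_median <- data.frame(ga_weeks = d$ga_weeks,
                          value = normal_centile(m, d$ga_weeks, 50))
  cov0 <- coverage(fn, at_median)
  expect_equal(cov0$observed_pct, c(0, 0))
  expect_equal(cov0$side, c("below", "above"))
  ## empty centile list gives an empty table
  expect_equal(nrow(coverage(fn, d, centiles = numeric(0))), 0L)
  ## simulated from the model itself: close to nominal with binomial CI
  set.seed(44)
  big <- data.frame(ga_weeks = runif(10000, 33, 42))
  big$value <- rnorm(10000, predict(m$mean_curve, big$ga_weeks),
                     m$sd_scale * predict(m$sd_curve, big$ga_weeks))
  covb <- coverage(fn, big)
  expect_equal(covb$observed_pct[1], 3, tolerance = 0.6)
  expect_true(covb$ci_lower[1] < 3 && covb$ci_upper[1] > 2)
  ## the binomial interval brackets the observed percentage
  expect_true(all(covb$ci_lower <= covb$observed_pct &
                    covb$observed_pct <= covb$ci_upper))
})

test_that("qq_data is the ordered Blom-position plot", {
  n <- 150
  z <- qnorm(((1:n) - 3 / 8) / (n + 1 / 4))
  qq <- qq_data(sample(z))
  expect_equal(qq$empirical, qq$theoretical, tolerance = 1e-12)
  expect_true(all(diff(qq$empirical) >= 0))
  set.seed(45)
  qt5 <- qq_data(rt(5000, 5))
  ## heavy upper tail departs above the line
  expect_gt(max(qt5$empirical), max(qt5$theoretical))
})

test_that("comparison_table ranks by the chosen criterion", {
  mk <- function(dev, df, n = 100) {
    structure(list(global_deviance = dev, df_total = df, n = n,
                   aic = dev + 2 * df, bic = dev + log(n) * df,
                   gaic_k = dev + 3 * df, k = 3,
                   coverage_3rd = 3, coverage_97th = 3),
              class = "fit_report")
  }
  reps <- list(x = mk(120, 2), y = mk(100, 8), z = mk(105, 4))
  tab <- comparison_table(reps, "gaic")
  manual <- names(sort(sapply(reps, function(r) r$gaic_k)))
  expect_equal(tab$model, manual)
  tab2 <- comparison_table(reps, "deviance", offset = 100)
  expect_equal(tab2$deviance[1], 0)
  expect_equal(tab2$model[1], "y")
  expect_error(comparison_table(list(mk(1, 1, 100), mk(1, 1, 200))),
               "different data")
  expect_equal(nrow(comparison_table(reps["x"])), 1L)
})

test_that("worm deviations shrink like 1/sqrt(n) for a true model", {
  dev_at <- function(n, seed) {
    set.seed(seed)
    w <- worm_data(rnorm(n), runif(n, 14, 42), n_groups = 1)
    mean(abs(w[[1]]$deviation))
  }
  d1 <- mean(sapply(1:5, function(s) dev_at(400, s)))
  d2 <- mean(sapply(1:5, function(s) dev_at(6400, s + 10)))
  ## 16x the data should shrink deviations by about 4x; allow slack
  expect_lt(d2, d1 / 2)
})
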