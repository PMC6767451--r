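test_that("cross-sectional CSV round-trips and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,ga_weeks,value",
               "a,M,39.5,3400",
               "b,M,40.1,3600",
               "c,M,not-a-number,3000",
               "d,F,38.2,3100"), path)
  rec <- read_records(path, "crosssec")
  expect_equal(nrow(rec), 3L)
  expect_length(attr(rec, "row_errors"), 1L)
  expect_match(attr(rec, "row_errors"), "line 4")

  ## clean round trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, out)
  again <- read_records(out, "crosssec")
  expect_equal(again$ga_weeks, rec$ga_weeks)
  expect_equal(again$value, rec$value)
})

test_that("longitudinal validation enforces the visit invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,visit,replicate,ga_weeks,value",
               "a,1,1,15.0,100", "a,1,2,15.0,101", "a,1,3,15.0,"), path)
  rec <- read_records(path, "longitudinal")
  expect_equal(sum(is.na(rec$value)), 1L) # empty value = missing replicate
  ## GA varying within a visit is rejected
  writeLines(c("id,visit,replicate,ga_weeks,value",
               "a,1,1,15.0,100", "a,1,2,15.5,101"), path)
  expect_error(read_records(path, "longitudinal"), "varies within")
  ## duplicate replicate rows are rejected
  writeLines(c("id,visit,replicate,ga_weeks,value",
               "a,1,1,15.0,100", "a,1,1,15.0,101"), path)
  expect_error(read_records(path, "longitudinal"), "duplicate")
  ## missing columns
  writeLines(c("id,ga_weeks,value", "a,15,100"), path)
  expect_error(read_records(path, "longitudinal"), "missing column")
})

test_that("chart tables are symmetric for normal models and never cross", {
  d <- sim_normal_crosssec(800, seed = 51)
  m <- fit_mean_sd(d)
  tab <- chart_table(m, c(3, 50, 97), seq(33, 42, by = 1))
  expect_equal(tab$p97 - tab$p50, tab$p50 - tab$p3, tolerance = 1e-9)
  expect_true(all(tab$p3 < tab$p50 & tab$p50 < tab$p97))
  ## crossing (from a negative SD region) is refused with the ages named
  bad <- structure(list(mean_curve = fp_spec(1, c(0, 0)),
                        sd_curve = fp_spec(1, c(10, -0.5)),
                        ga_range = c(14, 42)),
                   class = "multilevel_chart")
  expect_error(chart_table(bad, c(3, 97), c(15, 30, 41)), "cross")
  expect_error(chart_table(m, c(3, 97), c(40, 39)), "increasing")
})

test_that("written charts carry metadata and re-read identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_chart(published_fhc_chart(), path, c(3, 50, 97),
                     seq(14, 42, by = 1), metadata = list(units = "mm"))
  expect_equal(nrow(tab), 29L)
  expect_equal(tab$p50[tab$ga_weeks == 40], published_fhc(40, 50),
               tolerance = 1e-12)
  back <- read_chart(path)
  expect_equal(back$p50, tab$p50, tolerance = 1e-12)
  expect_equal(attr(back, "metadata")$units, "mm")
})

test_that("chart-model files reproduce evaluations bit-identically", {
  g <- seq(33.5, 41.5, by = 0.5)
  ## mean-SD model
  d <- sim_normal_crosssec(600, seed = 52)
  m <- fit_mean_sd(d)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_chart_model(m, p1)
  m2 <- read_chart_model(p1)
  expect_identical(normal_centile(m2, g, 3), normal_centile(m, g, 3))
  expect_identical(normal_zscore(m2, g, 3000), normal_zscore(m, g, 3000))
  ## distributional centile model (pspline + constants)
  db <- sim_family_crosssec(800, seed = 53, "BCCG", ga_lo = 33, ga_hi = 42,
                            function(t) list(mu = 70 * t, sigma = 0.1, nu = 1))
  cm <- fit_centile_model(db, "BCCG",
                          list(mu = curve_spec("pspline", edf = 3),
                               sigma = curve_spec("constant"),
                               nu = curve_spec("constant")))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_chart_model(cm, p2)
  cm2 <- read_chart_model(p2)
  expect_identical(suppressWarnings(model_centile(cm2, g, 97)),
                   suppressWarnings(model_centile(cm, g, 97)))
  expect_identical(model_sds(cm2, g, 2500), model_sds(cm, g, 2500))
  ## multilevel chart
  p3 <- withr::local_tempfile(fileext = ".json")
  write_chart_model(published_fhc_chart(), p3)
  ml <- read_chart_model(p3)
  expect_identical(multilevel_centile(ml, seq(14, 42, 2), 10),
                   suppressWarnings(published_fhc(seq(14, 42, 2), 10)))
})

test_that("the cli drives simulate/fit/centiles/zscore end to end", {
  dir <- withr::local_tempdir()
  cfg <- function(lines, name) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    p
  }
  data_csv <- file.path(dir, "sim.csv")
  model_json <- file.path(dir, "model.json")
  chart_csv <- file.path(dir, "chart.csv")
  c1 <- cfg(c("kind: crosssec", "n: 400", "seed: 5",
              sprintf("out: %s", data_csv)), "sim.yaml")
  expect_equal(suppressMessages(cli(c("simulate", "--config", c1))), 0L)
  expect_true(file.exists(data_csv))
  c2 <- cfg(c(sprintf("input: %s", data_csv), "method: meansd",
              sprintf("out: %s", model_json)), "fit.yaml")
  expect_equal(suppressMessages(cli(c("fit-crosssec", "--config", c2))), 0L)
  c3 <- cfg(c(sprintf("model: %s", model_json), "ga_min: 34", "ga_max: 41",
              "ga_step: 1", sprintf("out: %s", chart_csv)), "cent.yaml")
  expect_equal(suppressMessages(cli(c("centiles", "--config", c3))), 0L)
  tab <- read_chart(chart_csv)
  expect_equal(nrow(tab), 8L)
  ## zscore at the fitted median prints 0.00
  med <- tab$p50[tab$ga_weeks == 38]
  c4 <- cfg(c(sprintf("model: %s", model_json), "ga: 38",
              sprintf("value: %.10f", med)), "z.yaml")
  out <- capture.output(status <- suppressMessages(cli(c("zscore", "--config", c4))))
  expect_equal(status, 0L)
  expect_equal(out, "0.00")
  ## usage errors exit with status 2
  expect_equal(suppressMessages(cli(c("frobnicate", "--config", c1))), 2L)
  expect_equal(suppressMessages(cli(c("centiles", "--config",
                                      file.path(dir, "absent.yaml")))), 2L)
  expect_equal(suppressMessages(cli(character(0))), 2L)
})
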