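## ---- record validation ----------------------------------------------------

validate_crosssec <- function(records, require_id = FALSE) {
  need <- c("ga_weeks", "value")
  if (!all(need %in% names(records))) {
    stop(sprintf("cross-sectional records need columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  records$ga_weeks <- as.numeric(records$ga_weeks)
  records$value <- as.numeric(records$value)
  if (any(!is.finite(records$ga_weeks)) || any(records$ga_weeks <= 0)) {
    stop("'ga_weeks' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(records$value))) {
    stop("'value' contains missing or non-finite entries", call. = FALSE)
  }
  if (require_id && !"id" %in% names(records)) {
    stop("records need an 'id' column", call. = FALSE)
  }
  records
}

validate_longitudinal <- function(records) {
  need <- c("id", "visit", "replicate", "ga_weeks", "value")
  if (!all(need %in% names(records))) {
    stop(sprintf("longitudinal records need columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  records$ga_weeks <- as.numeric(records$ga_weeks)
  if (any(!is.finite(records$ga_weeks)) || any(records$ga_weeks <= 0)) {
    stop("'ga_weeks' must be positive and finite", call. = FALSE)
  }
  key <- paste(records$id, records$visit, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (id, visit, replicate) rows", call. = FALSE)
  }
  ## one GA per (id, visit)
  vk <- paste(records$id, records$visit, sep = "\r")
  ga_per_visit <- tapply(records$ga_weeks, vk, function(g) length(unique(g)))
  if (any(ga_per_visit > 1L)) {
    stop("gestational age varies within a (id, visit) pair", call. = FALSE)
  }
  records
}

#' Read growth records from CSV
#'
#' Two canonical dialects: cross-sectional (`id`, `sex`, `ga_weeks`, `value`;
#' one row per subject) and longitudinal (`id`, `visit`, `replicate`,
#' `ga_weeks`, `value`; one row per individual replicate, `value` may be
#' empty for missing replicates). Gestational age is exact decimal weeks.
#' Rows with unparseable numbers are dropped and reported in the
#' `"row_errors"` attribute.
#'
#' @param path CSV file path.
#' @param dialect `"crosssec"` or `"longitudinal"`.
#' @return Validated data frame; attribute `"row_errors"` holds a character
#'   vector of skipped-row descriptions (empty if none).
#' @export
read_records <- function(path, dialect = c("crosssec", "longitudinal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- if (dialect == "crosssec") c("id", "sex", "ga_weeks", "value") else
    c("id", "visit", "replicate", "ga_weeks", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  suppress_na <- function(x) suppressWarnings(as.numeric(x))
  ga <- suppress_na(raw$ga_weeks)
  value <- suppress_na(raw$value)
  errors <- character(0)
  if (dialect == "crosssec") {
    bad <- !is.finite(ga) | ga <= 0 | !is.finite(value)
    if (any(bad)) {
      errors <- sprintf("line %d: non-numeric or non-positive ga_weeks/value",
                        which(bad) + 1L)
    }
    out <- data.frame(id = raw$id[!bad], sex = raw$sex[!bad],
                      ga_weeks = ga[!bad], value = value[!bad],
                      stringsAsFactors = FALSE)
    out <- validate_crosssec(out, require_id = TRUE)
  } else {
    ## empty value = missing replicate (allowed); bad GA is a row error
    empty_val <- !nzchar(trimws(raw$value))
    value[empty_val] <- NA_real_
    bad <- !is.finite(ga) | ga <= 0 | (!empty_val & !is.finite(value))
    if (any(bad)) {
      errors <- sprintf("line %d: non-numeric ga_weeks/value", which(bad) + 1L)
    }
    out <- data.frame(id = raw$id[!bad],
                      visit = as.integer(suppress_na(raw$visit[!bad])),
                      replicate = as.integer(suppress_na(raw$replicate[!bad])),
                      ga_weeks = ga[!bad], value = value[!bad],
                      stringsAsFactors = FALSE)
    out <- validate_longitudinal(out)
  }
  attr(out, "row_errors") <- errors
  out
}

#' Write growth records to CSV
#'
#' @param records data frame of records.
#' @param path output path (written atomically).
#' @export
write_records <- function(records, path) {
  atomic_write(function(p) utils::write.csv(records, p, row.names = FALSE,
                                            na = ""), path)
  invisible(path)
}

atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
}

## ---- centile evaluation dispatch -----------------------------------------

#' Centile evaluation for any fitted chart model
#'
#' Generic front door used by [chart_table()]: dispatches to
#' [normal_centile()], [model_centile()] or [multilevel_centile()].
#'
#' @param model a fitted model object.
#' @param ga gestational age(s), exact weeks.
#' @param centile centile(s) in percent.
#' @return Measurement value(s).
#' @export
chart_centile <- function(model, ga, centile) UseMethod("chart_centile")

#' @export
chart_centile.mean_sd_model <- function(model, ga, centile) {
  normal_centile(model, ga, centile)
}

#' @export
chart_centile.centile_model <- function(model, ga, centile) {
  model_centile(model, ga, centile)
}

#' @export
chart_centile.multilevel_chart <- function(model, ga, centile) {
  multilevel_centile(model, ga, centile)
}

#' Chart table on a gestational-age grid
#'
#' Evaluates the requested centiles on a GA grid and verifies the defining
#' chart invariant: centile columns must increase left-to-right at every
#' age (centiles never cross).
#'
#' @param model a fitted chart model ([fit_mean_sd()],
#'   [fit_centile_model()], [multilevel_chart()], [published_fhc_chart()] or
#'   a model re-read by [read_chart_model()]).
#' @param centiles centiles in percent, e.g. `c(3, 10, 50, 90, 97)`.
#' @param ga_grid strictly increasing gestational-age grid (weeks).
#' @param metadata optional named list stored with the table.
#' @return Data frame of class `"chart_table"` with column `ga_weeks` and
#'   one `p<centile>` column per centile; metadata in attributes.
#' @export
chart_table <- function(model, centiles = c(3, 10, 50, 90, 97),
                        ga_grid, metadata = list()) {
  if (any(diff(ga_grid) <= 0)) {
    stop("'ga_grid' must be strictly increasing", call. = FALSE)
  }
  centiles <- sort(unique(centiles))
  tab <- data.frame(ga_weeks = ga_grid)
  for (cc in centiles) {
    tab[[sprintf("p%g", cc)]] <-
      suppressWarnings(as.numeric(chart_centile(model, ga_grid, cc)))
  }
  if (length(centiles) > 1L) {
    vals <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(apply(vals, 1L, function(r) any(diff(r) <= 0)))
    if (length(bad)) {
      stop(sprintf("centiles cross at gestational age(s): %s",
                   paste(round(ga_grid[bad], 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  attr(tab, "metadata") <- metadata
  class(tab) <- c("chart_table", "data.frame")
  tab
}

#' Write a chart table to CSV
#'
#' The metadata block is written as `# key: value` comment lines above the
#' header; the crossing check of [chart_table()] runs before anything is
#' written, and the file is written atomically.
#'
#' @inheritParams chart_table
#' @param path output CSV path.
#' @return The [chart_table()] invisibly.
#' @export
write_chart <- function(model, path, centiles = c(3, 10, 50, 90, 97),
                        ga_grid = seq(14, 42), metadata = list()) {
  tab <- chart_table(model, centiles, ga_grid, metadata)
  atomic_write(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    meta <- c(list(model_class = class(model)[1],
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
              metadata)
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
    }
    utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  }, path)
  invisible(tab)
}

#' Read a chart table written by [write_chart()]
#'
#' @param path CSV path.
#' @return A `"chart_table"` data frame with the metadata attribute.
#' @export
read_chart <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  tab <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  attr(tab, "metadata") <- meta
  class(tab) <- c("chart_table", "data.frame")
  tab
}

## ---- chart-model serialization -------------------------------------------

## numbers are stored as %.17g strings so that evaluations after a round
## trip are bit-identical
num_out <- function(x) if (is.null(x)) NULL else sprintf("%.17g", as.numeric(x))
num_in <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))

serialize_fp <- function(sp) {
  list(powers = num_out(sp$powers), coefficients = num_out(sp$coefficients),
       scale_shift = num_out(sp$scale_shift))
}
deserialize_fp <- function(obj) {
  fp_spec(num_in(obj$powers), num_in(obj$coefficients),
          num_in(obj$scale_shift) %||% 0)
}

#' Save a fitted chart model to a plain-text file
#'
#' JSON serialization of a [fit_mean_sd()], [fit_centile_model()] or
#' [multilevel_chart()] object — family, per-parameter curve kind,
#' powers/knots, coefficients, link and GA range — sufficient to recompute
#' any centile or Z-score bit-exactly after [read_chart_model()].
#'
#' @param model the fitted model.
#' @param path output path.
#' @export
write_chart_model <- function(model, path) {
  obj <- if (inherits(model, "mean_sd_model")) {
    list(type = "mean_sd",
         mean_curve = serialize_fp(model$mean_curve),
         sd_curve = serialize_fp(model$sd_curve),
         sd_scale = num_out(model$sd_scale), transform = model$transform,
         shift_k = num_out(model$shift_k), n_obs = model$n_obs,
         ga_range = num_out(model$ga_range))
  } else if (inherits(model, "centile_model")) {
    list(type = "centile",
         family = model$family,
         n_obs = model$n_obs,
         global_deviance = num_out(model$global_deviance),
         df_total = num_out(model$df_total),
         ga_range = num_out(model$ga_range),
         curves = lapply(model$curves, function(cv) {
           list(kind = cv$spec$kind,
                powers = num_out(cv$spec$powers),
                edf = num_out(cv$edf),
                n_basis = cv$spec$n_basis,
                knots = num_out(cv$knots),
                lambda = num_out(cv$lambda),
                coefficients = num_out(cv$coefficients),
                link = cv$link,
                ga_range = num_out(cv$ga_range))
         }))
  } else if (inherits(model, "multilevel_chart")) {
    list(type = "multilevel",
         model_kind = model$model_kind %||% "published",
         mean_curve = serialize_fp(model$mean_curve),
         sd_curve = serialize_fp(model$sd_curve),
         ga_range = num_out(model$ga_range))
  } else {
    stop("unsupported model class for serialization", call. = FALSE)
  }
  atomic_write(function(p)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, null = "null",
                         pretty = TRUE), path)
  invisible(path)
}

#' Load a chart model saved by [write_chart_model()]
#'
#' @param path model file path.
#' @return The reconstructed model object.
#' @export
read_chart_model <- function(path) {
  obj <- jsonlite::read_json(path)
  switch(obj$type,
    mean_sd = structure(list(
      mean_curve = deserialize_fp(obj$mean_curve),
      sd_curve = deserialize_fp(obj$sd_curve),
      sd_scale = num_in(obj$sd_scale), transform = obj$transform,
      shift_k = num_in(obj$shift_k), n_obs = obj$n_obs,
      ga_range = num_in(obj$ga_range)), class = "mean_sd_model"),
    centile = {
      curves <- lapply(obj$curves, function(cv) {
        spec <- if (cv$kind == "constant") curve_spec("constant")
        else if (cv$kind == "fp") curve_spec("fp", powers = num_in(cv$powers))
        else curve_spec("pspline", edf = num_in(cv$edf),
                        n_basis = as.integer(cv$n_basis))
        list(spec = spec, ga_range = num_in(cv$ga_range),
             knots = num_in(cv$knots), lambda = num_in(cv$lambda),
             edf = num_in(cv$edf), coefficients = num_in(cv$coefficients),
             link = cv$link)
      })
      names(curves) <- names(obj$curves)
      structure(list(family = obj$family, curves = curves,
                     n_obs = obj$n_obs,
                     global_deviance = num_in(obj$global_deviance),
                     df_total = num_in(obj$df_total),
                     ga_range = num_in(obj$ga_range)),
                class = "centile_model")
    },
    multilevel = structure(list(
      mean_curve = deserialize_fp(obj$mean_curve),
      sd_curve = deserialize_fp(obj$sd_curve),
      model_kind = obj$model_kind,
      ga_range = num_in(obj$ga_range)), class = "multilevel_chart"),
    stop(sprintf("unknown chart-model type: %s", obj$type), call. = FALSE))
}
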