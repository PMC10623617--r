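# Serialization: scenario specs and item banks as JSON, norm models as
# JSON, samples and norm tables as CSV, experiment configs as YAML.

#' Write and read scenario specifications as JSON
#'
#' Cell tables are keyed `"edu,eth,reg"` with percent values, one object
#' per cohort.
#'
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `read_scenario_json` returns a `scenario_spec`.
#' @export
write_scenario_json <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  cohorts <- lapply(spec$cohort_tables, function(tab) {
    keys <- paste(tab$education, tab$ethnicity, tab$region, sep = ",")
    as.list(stats::setNames(tab$pct, keys))
  })
  jsonlite::write_json(
    list(scenario = spec$scenario, params = spec$params, cohorts = cohorts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  tables <- lapply(obj$cohorts, function(cells) {
    keys <- do.call(rbind, strsplit(names(cells), ","))
    tab <- data.frame(education = as.integer(keys[, 1L]),
                      ethnicity = as.integer(keys[, 2L]),
                      region = as.integer(keys[, 3L]),
                      pct = as.numeric(unlist(cells)))
    tab[order(tab$region, tab$ethnicity, tab$education), ]
  })
  tables <- lapply(tables, function(t) { rownames(t) <- NULL; t })
  structure(list(scenario = as.integer(obj$scenario),
                 cohort_tables = tables,
                 params = lapply(obj$params, unlist)),
            class = "scenario_spec")
}

#' Write and read item banks as JSON
#'
#' Stores difficulties together with the seed and bounds, so an experiment
#' is fully replayable.
#'
#' @param bank An `item_bank`.
#' @param path File path.
#' @return `read_item_bank` returns an `item_bank`.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  jsonlite::write_json(unclass(bank), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(difficulties = as.numeric(obj$difficulties),
                 lo = obj$lo, hi = obj$hi, seed = as.integer(obj$seed)),
            class = "item_bank")
}

#' Write and read norm models as JSON
#'
#' Stores terms, coefficients, diagnostics and calibration ranges.
#'
#' @param model A `norm_model`.
#' @param path File path.
#' @return `read_norm_model` returns a `norm_model`.
#' @export
write_norm_model <- function(model, path) {
  stopifnot(inherits(model, "norm_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(terms = as.character(obj$terms),
                coefficients = as.list(obj$coefficients),
                k = as.integer(obj$k),
                calibration = lapply(obj$calibration, as.numeric),
                r2 = obj$r2, adj_r2 = obj$adj_r2,
                n_terms = as.integer(obj$n_terms),
                accepted = isTRUE(obj$accepted),
                monotone = isTRUE(obj$monotone),
                weighted = isTRUE(obj$weighted))
  class(model) <- "norm_model"
  model
}

#' Read a user normative sample from CSV
#'
#' Expects one row per person with numeric columns `age` and `raw` plus
#' any categorical columns to be raked.  A `cohort` column is derived
#' from `floor(age)` when absent, and `weight` is initialised to 1.
#'
#' @param path CSV file path.
#' @return A `norm_sample` data frame.
#' @export
read_norm_sample <- function(path) {
  sam <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("age", "raw")) {
    if (!col %in% names(sam)) {
      stop("sample CSV lacks required column '", col, "'", call. = FALSE)
    }
    if (!is.numeric(sam[[col]]) || anyNA(sam[[col]])) {
      stop("column '", col, "' must be numeric without missing values",
           call. = FALSE)
    }
  }
  if (!"cohort" %in% names(sam)) sam$cohort <- floor(sam$age)
  if (!"weight" %in% names(sam)) sam$weight <- 1
  class(sam) <- c("norm_sample", "data.frame")
  sam
}

#' Read marginal raking targets from YAML or JSON
#'
#' The file maps each variable to a mapping of category to proportion;
#' proportions per variable must sum to 1 (values summing to 100 are
#' interpreted as percentages and rescaled).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file path.
#' @return Named list of named numeric vectors, as for [rake_weights()].
#' @export
read_margin_targets <- function(path) {
  targets <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  targets <- lapply(targets, function(tv) {
    tv <- unlist(tv)
    if (abs(sum(tv) - 100) < 1e-6) tv <- tv / 100
    tv
  })
  .check_targets(targets)
  targets
}

#' Conventional norm table from a fitted model
#'
#' Tabulates the raw-to-norm-score mapping per age: for each age and each
#' raw score in `raws`, the model is inverted to the IQ metric.  Norm
#' scores are rounded only here, at the reporting layer.
#'
#' @param model A `norm_model`.
#' @param ages Ages at which to tabulate (e.g. cohort midpoints).
#' @param raws Raw scores to tabulate (default `0:31`).
#' @param digits Rounding for the reported norm score (default 0,
#'   i.e. integer IQ scores; use `NA` to disable).
#' @return Data frame with columns `age`, `raw`, `norm_score`, `clamped`.
#' @export
norm_table <- function(model, ages, raws = 0:31, digits = 0) {
  grid <- expand.grid(raw = raws, age = ages)
  ns <- predict_norm_score(model, grid$raw, grid$age)
  out <- data.frame(age = grid$age, raw = grid$raw,
                    norm_score = as.numeric(ns),
                    clamped = attr(ns, "clamped"))
  if (!is.na(digits)) out$norm_score <- round(out$norm_score, digits)
  out
}
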