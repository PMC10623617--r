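# Experiment orchestration: YAML configs, the replication driver, norming
# of user samples, and deterministic fixtures.  A thin command-line
# wrapper around these functions ships in inst/cli/wcnorm.R.

#' Write and read experiment configurations as YAML
#'
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(experiment_config, obj)
}

#' Run the replication experiment and write a results directory
#'
#' Runs [run_experiment()] and writes `results.csv` (tidy ErrorSummary),
#' `diagnostics.csv`, `config.lock.yaml` (the exact configuration,
#' including the master seed, for byte-identical re-runs),
#' `item_bank.json` and `summary.md` (headline contrasts).  Re-running on
#' the locked config reproduces `results.csv` exactly.
#'
#' @param config An `experiment_config`.
#' @param out_dir Output directory (created if needed).
#' @param progress Print per-scenario progress.
#' @return The `wcn_experiment`, invisibly.
#' @export
replicate_study <- function(config, out_dir, progress = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exp <- run_experiment(config, progress = progress)
  utils::write.csv(exp$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  if (!is.null(exp$failures)) {
    utils::write.csv(exp$failures, file.path(out_dir, "failures.csv"),
                     row.names = FALSE)
  }
  write_experiment_config(config, file.path(out_dir, "config.lock.yaml"))
  write_item_bank(exp$bank, file.path(out_dir, "item_bank.json"))
  s <- summarize_experiment(exp)
  lines <- c(
    "# Weighted vs. unweighted continuous norming -- summary", "",
    sprintf("Scenarios %s, %d replicates, %d cases/cohort, seed %d.",
            paste(config$scenarios, collapse = ", "), config$replicates,
            config$n_per_cohort, config$seed), "",
    "## Grand means (over populations, replicates and location bins)", "",
    sprintf("- %s: RMSE %.3f, MSD %+.3f IQ points",
            s$grand$method, s$grand$rmse, s$grand$msd), "",
    "## Per-population contrasts (SCN minus WCN; positive favours WCN)", "")
  for (i in seq_len(nrow(s$contrasts))) {
    ct <- s$contrasts[i, ]
    lines <- c(lines, sprintf(
      paste0("- population %d: dRMSE %+0.3f [%0.3f, %0.3f], ",
             "dMSD %+0.3f [%0.3f, %0.3f]%s"),
      ct$population, ct$d_rmse, ct$d_rmse_lo, ct$d_rmse_hi,
      ct$d_msd, ct$d_msd_lo, ct$d_msd_hi,
      if (ct$relevant) " (practically relevant, >= 1 IQ point)" else ""))
  }
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(exp)
}

#' Norm a user-supplied sample
#'
#' Applies the norming workflow to real data: optional raking against
#' user-supplied marginal targets, weighted percentile ranking, norm-model
#' fitting, per-person norm scores, and a conventional norm table per age
#' group.  Without targets only the unweighted model is produced.
#'
#' @param sample A `norm_sample` (from [read_norm_sample()]) or data frame
#'   with columns `age`, `raw` and any categorical columns to be raked.
#' @param targets Optional marginal targets (see [rake_weights()] and
#'   [read_margin_targets()]).
#' @param out_dir Optional output directory; when given, writes
#'   `sample_weighted.csv` (input plus weights), `person_norms.csv`,
#'   `norm_table_wcn.csv` / `norm_table_scn.csv` and model JSON files.
#' @param k,max_terms,r2_target Model settings (see [fit_norm_model()]).
#' @param rake_tol,rake_max_iter Raking settings.
#' @param weight_cap Warn when any standardized weight exceeds this value
#'   (default 3): large weights multiply the sampling error of small
#'   strata.
#' @param table_ages Ages for the norm table (default cohort midpoints
#'   present in the sample).
#' @return List with `wcn` and `scn` model objects (plus `weights`,
#'   `person_norms`, `norm_tables`).
#' @export
norm_user_sample <- function(sample, targets = NULL, out_dir = NULL,
                             k = 4L, max_terms = 12L, r2_target = 0.99,
                             rake_tol = 1e-6, rake_max_iter = 50L,
                             weight_cap = 3, table_ages = NULL) {
  if (!"cohort" %in% names(sample)) sample$cohort <- floor(sample$age)
  if (!"weight" %in% names(sample)) sample$weight <- 1
  class(sample) <- unique(c("norm_sample", class(sample)))
  if (is.null(table_ages)) table_ages <- sort(unique(sample$cohort)) + 0.5
  raw_range <- 0:max(sample$raw)

  out <- list()
  scn_ranked <- weighted_percentile_ranks(sample)
  out$scn <- fit_norm_model(scn_ranked, k = k, max_terms = max_terms,
                            r2_target = r2_target)
  person <- data.frame(age = sample$age, raw = sample$raw)
  iq_scn <- predict_norm_score(out$scn, sample$raw, sample$age)
  person$iq_scn <- as.numeric(iq_scn)

  if (!is.null(targets)) {
    w <- rake_weights(sample, targets, tol = rake_tol,
                      max_iter = rake_max_iter)
    sw <- standardize_weights(w)
    if (max(sw) > weight_cap) {
      warning(sprintf(paste0("largest standardized weight %.2f exceeds ",
                             "the cap of %.2f; weighted norms may amplify ",
                             "sampling error in small strata"),
                      max(sw), weight_cap), call. = FALSE)
    }
    wcn_sample <- sample
    wcn_sample$weight <- sw
    wcn_ranked <- weighted_percentile_ranks(wcn_sample)
    out$wcn <- fit_norm_model(wcn_ranked, k = k, max_terms = max_terms,
                              r2_target = r2_target)
    out$weights <- sw
    iq_wcn <- predict_norm_score(out$wcn, sample$raw, sample$age)
    person$iq_wcn <- as.numeric(iq_wcn)
  }
  out$person_norms <- person
  out$norm_tables <- list(scn = norm_table(out$scn, table_ages, raw_range))
  if (!is.null(out$wcn)) {
    out$norm_tables$wcn <- norm_table(out$wcn, table_ages, raw_range)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(person, file.path(out_dir, "person_norms.csv"),
                     row.names = FALSE)
    utils::write.csv(out$norm_tables$scn,
                     file.path(out_dir, "norm_table_scn.csv"),
                     row.names = FALSE)
    write_norm_model(out$scn, file.path(out_dir, "model_scn.json"))
    if (!is.null(out$wcn)) {
      sam_out <- as.data.frame(sample)
      sam_out$weight <- out$weights
      utils::write.csv(sam_out, file.path(out_dir, "sample_weighted.csv"),
                       row.names = FALSE)
      utils::write.csv(out$norm_tables$wcn,
                       file.path(out_dir, "norm_table_wcn.csv"),
                       row.names = FALSE)
      write_norm_model(out$wcn, file.path(out_dir, "model_wcn.json"))
    }
  }
  out
}

#' Write small deterministic fixtures
#'
#' Produces the miniature inputs used by the test suite and documentation:
#' one 50-row normative sample per scenario (CSV), a 31-item bank (JSON),
#' a toy reference population (CSV) and the scenario specifications
#' (JSON).  Identical seeds give byte-identical files.
#'
#' @param dir Output directory.
#' @param seed Integer seed (default 20230216).
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20230216L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .child_seeds(seed, 9L)
  paths <- character(0L)
  ref_spec <- scenario_cells(1L)
  toy_ref <- generate_population(ref_spec, 500L, seed = seeds[1L])
  moments <- reference_moments(toy_ref)
  bank <- draw_item_bank(seed = seeds[2L])
  p <- file.path(dir, "item_bank.json")
  write_item_bank(bank, p)
  paths <- c(paths, p)
  toy_ref$theta_pop <- standardize_ability(toy_ref$x1, moments)
  toy_ref$raw <- simulate_raw_scores(toy_ref$theta_pop, bank,
                                     seed = seeds[3L])
  p <- file.path(dir, "toy_reference.csv")
  utils::write.csv(format(toy_ref, digits = 10), p, row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, p)
  for (s in 1:6) {
    spec <- scenario_cells(s)
    p <- file.path(dir, sprintf("scenario_%d.json", s))
    write_scenario_json(spec, p)
    paths <- c(paths, p)
    sam <- draw_norm_sample(spec, moments, bank, n_per_cohort = 9L,
                            seed = seeds[3L + s])
    sam <- sam[sample.int(nrow(sam), 50L), ]
    p <- file.path(dir, sprintf("sample_scenario_%d.csv", s))
    utils::write.csv(format(sam, digits = 10), p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
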