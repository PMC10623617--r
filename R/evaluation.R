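# Scoring fitted norm models against the benchmark: RMSE and MSD overall
# and within 11 person-location bins, and the replicated simulation
# experiment comparing weighted (WCN) with unweighted (SCN) norming.

#' Root mean square error in IQ points
#'
#' `sqrt(mean((predicted - best)^2))`: total norm-score error, combining
#' systematic bias and variable error.
#'
#' @param predicted,best Equal-length numeric vectors of norm scores.
#' @return RMSE in IQ points.
#' @export
rmse <- function(predicted, best) {
  if (length(predicted) == 0L || length(predicted) != length(best)) {
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  }
  sqrt(mean((predicted - best)^2))
}

#' Mean signed difference in IQ points
#'
#' `mean(predicted - best)`: the tendency of a norming model to
#' overestimate (`MSD > 0`) or underestimate (`MSD < 0`) the actual person
#' location.
#'
#' @inheritParams rmse
#' @return MSD in IQ points.
#' @export
msd <- function(predicted, best) {
  if (length(predicted) == 0L || length(predicted) != length(best)) {
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  }
  mean(predicted - best)
}

#' Assign person-location bins
#'
#' Bins norm scores into 11 intervals of 7.5 IQ points with midpoints
#' 62.5, 70, ..., 137.5 (edges 58.75 to 141.25).  Values outside the
#' binned range get `NA` (they are excluded from bin-wise summaries but
#' retained in overall ones).
#'
#' @param iq Numeric vector of norm scores.
#' @return Integer bin ids 1-11 (or `NA`), with attribute `"midpoints"`.
#' @export
#' @examples
#' assign_location_bins(c(100, 62.5, 150))
assign_location_bins <- function(iq) {
  bin <- floor((iq - 58.75) / 7.5) + 1
  bin[iq < 58.75 | iq >= 141.25] <- NA_integer_
  structure(as.integer(bin), midpoints = 55 + 7.5 * (1:11))
}

#' Evaluation set drawn from the reference population
#'
#' A fixed random subsample of the reference population carrying age, raw
#' score and benchmark norm score.  Every population, method and replicate
#' is scored on the same evaluees, so that person-location bins are
#' populated across the full reference ability range.
#'
#' @param pop Reference `population_table` with a `raw` column.
#' @param norms `benchmark_norms` computed on `pop`.
#' @param size Number of evaluees (default 20000).
#' @param seed Integer seed.
#' @return Data frame with columns `age`, `raw`, `iq_best`.
#' @export
draw_evaluation_set <- function(pop, norms, size = 20000L, seed) {
  stopifnot(inherits(norms, "benchmark_norms"),
            length(norms$iq_best) == nrow(pop))
  set.seed(as.integer(seed))
  ix <- sample.int(nrow(pop), min(size, nrow(pop)))
  data.frame(age = pop$age[ix], raw = pop$raw[ix],
             iq_best = norms$iq_best[ix])
}

#' Score a norm model against the benchmark
#'
#' Predicts a norm score for every evaluee from raw score and age and
#' summarises `predicted - IQ_best` by RMSE and MSD, overall and within
#' each person-location bin of the benchmark score.
#'
#' @param model A `norm_model`.
#' @param evalset Evaluation set from [draw_evaluation_set()] (columns
#'   `age`, `raw`, `iq_best`).
#' @param interval,tol Passed to [predict_norm_score()].
#' @return Data frame with columns `bin` (`"overall"` or the bin
#'   midpoint), `rmse`, `msd`, `n`.
#' @export
evaluate_model <- function(model, evalset, interval = c(40, 160),
                           tol = 1e-4) {
  pred <- predict_norm_score(model, evalset$raw, evalset$age,
                             interval = interval, tol = tol)
  best <- evalset$iq_best
  bin <- assign_location_bins(best)
  mids <- attr(bin, "midpoints")
  rows <- data.frame(bin = "overall", rmse = rmse(pred, best),
                     msd = msd(pred, best), n = length(best),
                     stringsAsFactors = FALSE)
  for (b in seq_along(mids)) {
    ix <- which(!is.na(bin) & bin == b)
    if (length(ix) == 0L) next
    rows <- rbind(rows, data.frame(
      bin = format(mids[b]), rmse = rmse(pred[ix], best[ix]),
      msd = msd(pred[ix], best[ix]), n = length(ix),
      stringsAsFactors = FALSE))
  }
  rows
}

#' Experiment configuration
#'
#' Collects every parameter of the simulation experiment with the study
#' defaults, so a run is fully specified by its configuration and master
#' seed.  The master seed spawns per-component child seeds (population,
#' item bank, samples, evaluation set), making components independently
#' reproducible.
#'
#' @param scenarios Scenario ids to run (default 1:6).
#' @param replicates Normative samples per scenario (default 100).
#' @param n_per_cohort Sample cases per cohort (default 100, i.e. 600 per
#'   sample).
#' @param n_ref_per_cohort Reference-population size per cohort (default
#'   4e6 at full scale; reduced profiles are routinely used).
#' @param eval_size Evaluation-set size (default 20000).
#' @param n_items,item_lo,item_hi Item-bank specification (default 31
#'   items on \[-3, 3\]).
#' @param k,max_terms,r2_target Norm-model settings (defaults 4, 12,
#'   0.99).
#' @param rake_tol,rake_max_iter Raking settings (defaults 1e-6, 50).
#' @param groups_per_cohort Benchmark age groups per cohort (default 365).
#' @param scenario5_perturbation Scenario-5 cell perturbation in
#'   percentage points (default 0.15).
#' @param seed Master seed (required; no silent nondeterminism).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(scenarios = 1:6, replicates = 100L,
                              n_per_cohort = 100L, n_ref_per_cohort = 4e6,
                              eval_size = 20000L, n_items = 31L,
                              item_lo = -3, item_hi = 3, k = 4L,
                              max_terms = 12L, r2_target = 0.99,
                              rake_tol = 1e-6, rake_max_iter = 50L,
                              groups_per_cohort = 365L,
                              scenario5_perturbation = 0.15, seed) {
  if (missing(seed)) stop("a master seed is required", call. = FALSE)
  cfg <- list(scenarios = as.integer(scenarios),
              replicates = as.integer(replicates),
              n_per_cohort = as.integer(n_per_cohort),
              n_ref_per_cohort = as.integer(n_ref_per_cohort),
              eval_size = as.integer(eval_size),
              n_items = as.integer(n_items),
              item_lo = item_lo, item_hi = item_hi,
              k = as.integer(k), max_terms = as.integer(max_terms),
              r2_target = r2_target, rake_tol = rake_tol,
              rake_max_iter = as.integer(rake_max_iter),
              groups_per_cohort = as.integer(groups_per_cohort),
              scenario5_perturbation = scenario5_perturbation,
              seed = as.integer(seed))
  counts <- c("replicates", "n_per_cohort", "n_ref_per_cohort", "eval_size",
              "n_items", "k", "max_terms", "rake_max_iter",
              "groups_per_cohort")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(f, " must be at least 1", call. = FALSE)
  }
  if (!all(cfg$scenarios %in% 1:6)) {
    stop("scenarios must be within 1..6", call. = FALSE)
  }
  class(cfg) <- "experiment_config"
  cfg
}

# Derive reproducible child seeds from the master seed.
.child_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Build the shared reference objects of an experiment
#'
#' Generates the scenario-1 reference population, its moments, the shared
#' item bank, reference raw scores, benchmark norms and the evaluation
#' set.  [run_experiment()] calls this internally; it is exported so the
#' expensive reference stage can be reused across analyses.
#'
#' @param config An `experiment_config`.
#' @param keep_population If `TRUE`, the reference population table is
#'   returned as well (it can be large).
#' @return List with `moments`, `bank`, `evalset`, `norms_table`,
#'   `ref_spec`, and optionally `population`.
#' @export
build_reference <- function(config, keep_population = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- .child_seeds(config$seed, 4L)
  ref_spec <- scenario_cells(1L)
  pop <- generate_population(ref_spec, config$n_ref_per_cohort,
                             seed = seeds[1L])
  moments <- reference_moments(pop)
  bank <- draw_item_bank(config$n_items, config$item_lo, config$item_hi,
                         seed = seeds[2L])
  pop$theta_pop <- standardize_ability(pop$x1, moments)
  pop$raw <- simulate_raw_scores(pop$theta_pop, bank, seed = seeds[3L])
  norms <- compute_iq_best(pop, config$groups_per_cohort)
  evalset <- draw_evaluation_set(pop, norms, config$eval_size,
                                 seed = seeds[4L])
  out <- list(moments = moments, bank = bank, evalset = evalset,
              norms_table = norms$table, ref_spec = ref_spec)
  if (keep_population) {
    pop$iq_best <- norms$iq_best
    out$population <- pop
  }
  out
}

#' Run the weighted-vs-unweighted norming experiment
#'
#' Executes the full simulation: for each population scenario and
#' replicate, a normative sample of `6 * n_per_cohort` cases is drawn,
#' raking weights against the reference marginals are computed (WCN) or
#' unit weights kept (SCN), both norm models are fitted, and both are
#' scored against the shared benchmark evaluation set, overall and within
#' the 11 person-location bins.
#'
#' Per-replicate failures (e.g. a non-convergent model) are recorded in
#' the `failures` element and skipped, never silently dropped.
#'
#' @param config An `experiment_config`.
#' @param reference Optionally, a prebuilt result of [build_reference()]
#'   for this configuration (to share the reference stage across runs).
#' @param progress If `TRUE`, print one line per scenario.
#' @return An object of class `wcn_experiment`: list with `results` (tidy
#'   data frame: `population`, `method`, `replicate`, `bin`, `rmse`,
#'   `msd`, `n`), `diagnostics` (per fit: terms, R-squared, raking
#'   iterations, max weight), `failures`, `config`, `bank`, `moments`.
#' @export
run_experiment <- function(config, reference = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(reference)) reference <- build_reference(config)
  targets <- margin_targets()
  rep_seeds <- matrix(
    .child_seeds(config$seed + 1L, 6L * config$replicates),
    nrow = 6L)
  results <- list()
  diagnostics <- list()
  failures <- list()
  for (s in config$scenarios) {
    if (progress) {
      message(sprintf("scenario %d: %d replicate(s) x 2 methods ...",
                      s, config$replicates))
    }
    spec <- scenario_cells(s, perturbation = config$scenario5_perturbation)
    for (r in seq_len(config$replicates)) {
      res <- tryCatch({
        sam <- draw_norm_sample(spec, reference$moments, reference$bank,
                                config$n_per_cohort,
                                seed = rep_seeds[s, r])
        w <- rake_weights(sam, targets, tol = config$rake_tol,
                          max_iter = config$rake_max_iter)
        wcn_sam <- sam
        wcn_sam$weight <- standardize_weights(w)
        out_rows <- list()
        diag_rows <- list()
        for (method in c("WCN", "SCN")) {
          msam <- if (method == "WCN") wcn_sam else sam
          ranked <- weighted_percentile_ranks(msam)
          model <- fit_norm_model(ranked, k = config$k,
                                  max_terms = config$max_terms,
                                  r2_target = config$r2_target)
          ev <- evaluate_model(model, reference$evalset)
          ev <- cbind(population = s, method = method, replicate = r, ev)
          out_rows[[method]] <- ev
          diag_rows[[method]] <- data.frame(
            population = s, method = method, replicate = r,
            n_terms = model$n_terms, r2 = model$r2, adj_r2 = model$adj_r2,
            accepted = model$accepted,
            rake_iterations = attr(w, "iterations"),
            rake_max_discrepancy = attr(w, "max_discrepancy"),
            max_weight = max(wcn_sam$weight))
        }
        list(rows = do.call(rbind, out_rows),
             diag = do.call(rbind, diag_rows))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          population = s, replicate = r,
          message = conditionMessage(res))
      } else {
        results[[length(results) + 1L]] <- res$rows
        diagnostics[[length(diagnostics) + 1L]] <- res$diag
      }
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  structure(list(results = results,
                 diagnostics = do.call(rbind, diagnostics),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 config = config, bank = reference$bank,
                 moments = reference$moments),
            class = "wcn_experiment")
}

#' Summarise an experiment into headline contrasts
#'
#' Aggregates the tidy per-replicate results the way the simulation study
#' reports them: replicate-level per-bin RMSE/MSD are averaged over
#' replicates (cell means), then over the 11 bins within a population,
#' then over populations.  Bootstrap percentile intervals over replicates
#' quantify the Monte-Carlo uncertainty of each cell mean difference.
#'
#' @param experiment A `wcn_experiment` (or its `results` data frame).
#' @param boot Bootstrap resamples for the WCN-SCN contrast intervals
#'   (default 2000; 0 disables).
#' @param conf Confidence level (default 0.95).
#' @param relevance Practical-relevance threshold in IQ points (default
#'   1): contrasts at least this large are flagged.
#' @return List with `by_population` (per population and method: mean
#'   RMSE/MSD over bins and replicates), `contrasts` (per population:
#'   `d_rmse = RMSE(SCN) - RMSE(WCN)`, `d_msd`, bootstrap intervals,
#'   `relevant` flag) and `grand` (grand means per method).
#' @export
summarize_experiment <- function(experiment, boot = 2000L, conf = 0.95,
                                 relevance = 1) {
  res <- if (inherits(experiment, "wcn_experiment")) experiment$results
         else experiment
  res <- res[res$bin != "overall", , drop = FALSE]
  # replicate-level mean over bins, then mean over replicates
  rep_mean <- stats::aggregate(
    res[, c("rmse", "msd")],
    by = res[, c("population", "method", "replicate")], FUN = mean)
  by_pop <- stats::aggregate(rep_mean[, c("rmse", "msd")],
                             by = rep_mean[, c("population", "method")],
                             FUN = mean)
  grand <- stats::aggregate(by_pop[, c("rmse", "msd")],
                            by = by_pop["method"], FUN = mean)
  contrasts <- NULL
  alpha <- (1 - conf) / 2
  for (s in unique(rep_mean$population)) {
    wcn <- rep_mean[rep_mean$population == s & rep_mean$method == "WCN", ]
    scn <- rep_mean[rep_mean$population == s & rep_mean$method == "SCN", ]
    wcn <- wcn[order(wcn$replicate), ]
    scn <- scn[order(scn$replicate), ]
    d_rmse <- scn$rmse - wcn$rmse
    d_msd <- scn$msd - wcn$msd
    row <- data.frame(population = s,
                      d_rmse = mean(d_rmse), d_msd = mean(d_msd))
    if (boot > 0L) {
      bs <- replicate(boot, {
        ix <- sample.int(length(d_rmse), replace = TRUE)
        c(mean(d_rmse[ix]), mean(d_msd[ix]))
      })
      qs <- apply(bs, 1L, stats::quantile, probs = c(alpha, 1 - alpha))
      row$d_rmse_lo <- qs[1L, 1L]; row$d_rmse_hi <- qs[2L, 1L]
      row$d_msd_lo <- qs[1L, 2L]; row$d_msd_hi <- qs[2L, 2L]
    }
    row$relevant <- abs(row$d_rmse) >= relevance | abs(row$d_msd) >= relevance
    contrasts <- rbind(contrasts, row)
  }
  list(by_population = by_pop, contrasts = contrasts, grand = grand)
}

#' @export
print.wcn_experiment <- function(x, ...) {
  cat("Weighted-vs-unweighted continuous norming experiment\n")
  cat(sprintf("  scenarios: %s; %d replicate(s); seed %d\n",
              paste(x$config$scenarios, collapse = ", "),
              x$config$replicates, x$config$seed))
  n_fail <- if (is.null(x$failures)) 0L else nrow(x$failures)
  cat(sprintf("  %d result row(s); %d failed replicate(s)\n",
              nrow(x$results), n_fail))
  s <- summarize_experiment(x, boot = 0L)
  g <- s$grand
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s: mean RMSE %.2f, mean MSD %+.2f IQ points\n",
                g$method[i], g$rmse[i], g$msd[i]))
  }
  invisible(x)
}
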