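# Normative-sample drawing and raking (iterative proportional fitting)
# post-stratification weights.

#' Draw a stratified normative sample
#'
#' Draws `n_per_cohort` persons per one-year cohort from a population
#' scenario's generative distribution (age, demographic cell, latent
#' ability), standardizes ability with the *reference* moments, and
#' simulates raw test scores with the shared item bank.  This mirrors a
#' norming study collecting 100 cases per age year (600 in total).
#'
#' @param spec A `scenario_spec` from [scenario_cells()].
#' @param moments `reference_moments` of the scenario-1 population.
#' @param bank An `item_bank`.
#' @param n_per_cohort Cases per cohort (default 100).
#' @param seed Integer seed.
#' @return A `norm_sample` data frame with columns `age`, `cohort`,
#'   `education`, `ethnicity`, `region`, `x1`, `theta_pop`, `raw` and
#'   `weight` (initialised to 1).
#' @export
draw_norm_sample <- function(spec, moments, bank, n_per_cohort = 100L, seed) {
  if (n_per_cohort < 2) stop("n_per_cohort must be at least 2", call. = FALSE)
  sam <- generate_population(spec, n_per_cohort, seed = seed)
  sam$theta_pop <- standardize_ability(sam$x1, moments)
  # raw-score draws continue the same RNG stream
  raw_seed <- sample.int(.Machine$integer.max, 1L)
  sam$raw <- simulate_raw_scores(sam$theta_pop, bank, seed = raw_seed)
  sam$weight <- 1
  class(sam) <- c("norm_sample", "data.frame")
  sam
}

.check_targets <- function(targets) {
  if (!is.list(targets) || is.null(names(targets)) ||
      any(!nzchar(names(targets)))) {
    stop("targets must be a named list of named proportion vectors",
         call. = FALSE)
  }
  for (v in names(targets)) {
    tv <- targets[[v]]
    if (is.null(names(tv)) || any(!nzchar(names(tv)))) {
      stop("targets for '", v, "' must be a named numeric vector",
           call. = FALSE)
    }
    if (any(tv <= 0)) {
      stop("targets for '", v, "' must all be positive", call. = FALSE)
    }
    if (abs(sum(tv) - 1) > 1e-9) {
      stop("targets for '", v, "' must sum to 1", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Raking (iterative proportional fitting) weights
#'
#' Computes post-stratification weights by raking: for one demographic
#' variable at a time, the weights of each category are rescaled so that
#' the weighted category proportion matches the population target, and the
#' sweep over variables is repeated until no weighted marginal deviates
#' from its target by more than `tol`.  Only marginal distributions enter;
#' joint targets can be raked by recoding a cross-classification into a
#' single variable whose levels are the joint cells.
#'
#' On convergence the post-stratification identity holds for every
#' category: `sum(w[in category]) / sum(w)` equals the target proportion.
#'
#' @param sample Data frame holding one column per variable named in
#'   `targets` (any categorical coding; values are matched by
#'   `as.character`).
#' @param targets Named list: per variable, a named vector of target
#'   proportions summing to 1 (see [margin_targets()]).
#' @param tol Convergence tolerance on the maximum absolute difference
#'   between weighted marginals and targets (default `1e-6`).
#' @param max_iter Maximum number of sweeps over all variables (default
#'   50).
#' @param weights Optional starting weights (default all 1).
#' @return Numeric vector of strictly positive weights (mean preserved at
#'   the scale reached by IPF), with attributes `iterations` and
#'   `max_discrepancy`.  Use [standardize_weights()] to rescale so the
#'   most overrepresented group has weight 1.
#' @export
#' @examples
#' d <- data.frame(education = rep(c("low", "medium", "high"), c(52, 20, 28)))
#' w <- rake_weights(d, list(education = c(low = .4, medium = .2, high = .4)))
#' tapply(w, d$education, unique)
rake_weights <- function(sample, targets, tol = 1e-6, max_iter = 50L,
                         weights = NULL) {
  .check_targets(targets)
  n <- nrow(sample)
  if (is.null(n) || n == 0L) stop("sample is empty", call. = FALSE)
  vars <- names(targets)
  missing_cols <- setdiff(vars, names(sample))
  if (length(missing_cols)) {
    stop("sample lacks raking variable(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  memb <- list()
  for (v in vars) {
    obs <- as.character(sample[[v]])
    cats <- names(targets[[v]])
    absent <- setdiff(cats, unique(obs))
    if (length(absent)) {
      stop("category '", absent[1L], "' of variable '", v,
           "' has no observations in the sample; raking targets are ",
           "unreachable", call. = FALSE)
    }
    extra <- setdiff(unique(obs), cats)
    if (length(extra)) {
      stop("sample contains category '", extra[1L], "' of variable '", v,
           "' that is missing from the targets", call. = FALSE)
    }
    memb[[v]] <- lapply(cats, function(ct) which(obs == ct))
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    stop("starting weights must be positive and match the sample size",
         call. = FALSE)
  }
  max_disc <- function(w) {
    tot <- sum(w)
    max(unlist(lapply(vars, function(v) {
      props <- vapply(memb[[v]], function(ix) sum(w[ix]), 0) / tot
      abs(props - targets[[v]])
    })))
  }
  iter <- 0L
  disc <- max_disc(w)
  while (disc > tol && iter < max_iter) {
    for (v in vars) {
      # classic raking step: rescale all of one variable's categories at
      # once so its weighted marginal matches the target exactly
      tot <- sum(w)
      tv <- targets[[v]]
      for (ci in seq_along(tv)) {
        ix <- memb[[v]][[ci]]
        w[ix] <- w[ix] * (tv[[ci]] * tot / sum(w[ix]))
      }
    }
    iter <- iter + 1L
    disc <- max_disc(w)
  }
  if (disc > tol) {
    stop(sprintf(paste0("raking did not converge after %d iterations ",
                        "(max marginal discrepancy %.3g > tol %.3g)"),
                 iter, disc, tol), call. = FALSE)
  }
  structure(w, iterations = iter, max_discrepancy = disc)
}

#' Standardize raking weights
#'
#' Divides every weight by the smallest weight so that the most
#' overrepresented group in the sample gets weight exactly 1 and every
#' weight is at least 1.  Weight ratios -- and hence every weighted
#' proportion and weighted regression fit -- are unchanged.  The operation
#' is idempotent.
#'
#' @param weights Numeric vector of strictly positive weights.
#' @return Rescaled weights with minimum exactly 1.
#' @export
#' @examples
#' standardize_weights(c(0.7692, 1, 1.4286))
standardize_weights <- function(weights) {
  w <- as.numeric(weights)
  if (length(w) == 0L || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  w / min(w)
}
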