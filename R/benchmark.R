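# Benchmark norms: IQ_best computed from the reference population by
# within-age-group rank-based inverse normal transformation, plus an
# analytic (quadrature) oracle for the exact raw-score distribution.

#' Benchmark norm scores (IQ_best) from a reference population
#'
#' Sorts each one-year cohort by continuous age and splits it into
#' `groups_per_cohort` equal-sized contiguous age groups (365 per cohort in
#' the full-scale design, i.e. 2,190 groups of same-"birthday"
#' individuals).  Within each group, raw scores are ranked with the
#' tie-averaged mid-rank rule and converted to IQ scores by the inverse
#' normal transformation, giving every individual -- and every raw value
#' occurring in the group -- a benchmark norm score `IQ_best`.
#'
#' @param pop A `population_table` carrying a `raw` column (see
#'   [simulate_raw_scores()]).
#' @param groups_per_cohort Number of equal-sized age groups per cohort
#'   (default 365).
#' @return A `benchmark_norms` object: list with `iq_best` (per-person
#'   vector aligned with `pop` rows), `group` (per-person group id,
#'   `1..6 * groups_per_cohort`), `table` (data frame `group`, `cohort`,
#'   `age_lo`, `age_hi`, `raw`, `iq_best`, `n`), and `groups_per_cohort`.
#'   Groups containing a single distinct raw value map it to IQ 100 and
#'   are counted in the `degenerate_groups` element.
#' @export
compute_iq_best <- function(pop, groups_per_cohort = 365L) {
  stopifnot(is.data.frame(pop), all(c("age", "cohort", "raw") %in% names(pop)))
  if (groups_per_cohort < 1) {
    stop("groups_per_cohort must be at least 1", call. = FALSE)
  }
  g <- as.integer(groups_per_cohort)
  n <- nrow(pop)
  group <- integer(n)
  for (j in unique(pop$cohort)) {
    ix <- which(pop$cohort == j)
    r <- rank(pop$age[ix], ties.method = "first")
    group[ix] <- j * g + pmin(g, floor((r - 1) * g / length(ix)) + 1L)
  }
  group <- group + 1L - min(group)   # 1-based over cohorts present

  # Vectorised within-group mid-rank percentiles: order by (group, raw),
  # aggregate counts per distinct (group, raw) pair, cumulate within group.
  o <- order(group, pop$raw)
  gs <- group[o]
  rs <- pop$raw[o]
  new_pair <- c(TRUE, gs[-1L] != gs[-n] | rs[-1L] != rs[-n])
  pair_id <- cumsum(new_pair)
  cnt <- tabulate(pair_id)                     # persons per (group, raw)
  pair_grp <- gs[new_pair]
  pair_raw <- rs[new_pair]
  grp_size <- tabulate(group)
  before <- cumsum(cnt) - cnt                  # persons before pair, overall
  first_in_grp <- c(TRUE, pair_grp[-1L] != pair_grp[-length(pair_grp)])
  grp_index <- cumsum(first_in_grp)
  grp_start <- before[first_in_grp][grp_index] # persons before pair's group
  below <- before - grp_start                  # persons below, within group
  p_pair <- (below + 0.5 * cnt) / grp_size[pair_grp]
  iq_pair <- 100 + 15 * stats::qnorm(p_pair)
  pairs_per_grp <- tabulate(grp_index)         # distinct raw values per group

  iq_best <- numeric(n)
  iq_best[o] <- iq_pair[pair_id]

  age_lo <- tapply(pop$age, group, min)
  age_hi <- tapply(pop$age, group, max)
  tab <- data.frame(
    group = pair_grp,
    cohort = (pair_grp - 1L) %/% g,
    age_lo = as.numeric(age_lo[as.character(pair_grp)]),
    age_hi = as.numeric(age_hi[as.character(pair_grp)]),
    raw = pair_raw,
    iq_best = iq_pair,
    n = cnt
  )
  structure(list(iq_best = iq_best, group = group, table = tab,
                 groups_per_cohort = g,
                 degenerate_groups = sum(pairs_per_grp == 1L)),
            class = "benchmark_norms")
}

#' @export
print.benchmark_norms <- function(x, ...) {
  cat(sprintf(
    "Benchmark norms: %d age groups (%d per cohort), %d persons\n",
    length(unique(x$group)), x$groups_per_cohort, length(x$iq_best)))
  if (x$degenerate_groups > 0) {
    cat("  note:", x$degenerate_groups,
        "group(s) contain a single raw value (IQ_best = 100)\n")
  }
  invisible(x)
}

#' Exact raw-score distribution at an age (quadrature)
#'
#' Computes the exact distribution of the 31-item raw score at a given age
#' under the scenario generative model: a mixture over the 27 demographic
#' cells of Poisson-binomial raw-score distributions, with the
#' standardized ability integrated over its normal distribution around the
#' cell mean.  Used as the analytic oracle for [compute_iq_best()] and
#' [analytic_iq_best()].
#'
#' @param age Age in years (scalar).
#' @param spec A `scenario_spec` (scenario 1 for reference norms).
#' @param bank An `item_bank`.
#' @param moments `reference_moments` used for standardization.
#' @param n_nodes Number of quadrature nodes on the latent deviate
#'   (default 201 over \[-8, 8\]).
#' @return Numeric vector of probabilities for raw scores `0..n_items`,
#'   summing to 1.
#' @export
raw_score_distribution <- function(age, spec, bank, moments,
                                   n_nodes = 201L) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(bank, "item_bank"),
            length(age) == 1L)
  tab <- spec$cohort_tables[[min(floor(age), 5) + 1L]]
  z <- seq(-8, 8, length.out = n_nodes)
  wz <- stats::dnorm(z)
  wz <- wz / sum(wz)
  mu_cell <- cell_mean(age, tab$education, tab$ethnicity, tab$region)
  # thetas for every (cell, node) combination
  theta <- standardize_ability(outer(mu_cell, z, `+`), moments)
  theta <- as.vector(theta)
  wmix <- as.vector(outer(tab$pct / 100, wz))
  keep <- wmix > 0
  theta <- theta[keep]
  wmix <- wmix[keep]
  n_items <- length(bank$difficulties)
  # Poisson-binomial DP vectorised over thetas
  P <- matrix(0, length(theta), n_items + 1L)
  P[, 1L] <- 1
  for (d in bank$difficulties) {
    p <- stats::plogis(theta - d)
    P <- cbind(P[, 1L] * (1 - p),
               P[, -c(1L, n_items + 1L), drop = FALSE] * (1 - p) +
                 P[, -c(n_items, n_items + 1L), drop = FALSE] * p,
               P[, n_items + 1L] * p)
  }
  as.vector(crossprod(P, wmix))
}

#' Analytic benchmark norm score
#'
#' The exact-population counterpart of [compute_iq_best()]: from the
#' quadrature raw-score distribution at the given age, the mid-
#' distribution percentile `P(X < raw) + 0.5 P(X = raw)` is mapped through
#' the inverse normal transformation to the IQ metric.  Serves as the
#' convergence oracle for the empirical benchmark.
#'
#' @param raw Raw score(s) `0..n_items`.
#' @inheritParams raw_score_distribution
#' @return `IQ_best` values (strictly increasing in `raw` at fixed age).
#' @export
analytic_iq_best <- function(raw, age, spec, bank, moments, n_nodes = 201L) {
  pmf <- raw_score_distribution(age, spec, bank, moments, n_nodes)
  cdf_below <- c(0, cumsum(pmf))[seq_along(pmf)]
  p <- cdf_below[raw + 1L] + 0.5 * pmf[raw + 1L]
  100 + 15 * stats::qnorm(p)
}
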