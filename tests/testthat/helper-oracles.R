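# Independent oracles and shared fixtures for the test suite.  Oracles are
# deliberately written from first principles (enumeration, quadrature,
# covariance algebra, array-based IPF) and never call the code paths they
# check.

# --- closed-form / quadrature oracles on the generative model -----------

# Enumerate the 27 demographic cells of the reference population with
# their probabilities and within-age ability means (the demographic part
# of the ability surface, no age terms).
oracle_cells <- function(edu = c(.4, .2, .4), eth = c(.3, .4, .3),
                         reg = c(.2, .2, .6)) {
  g <- expand.grid(e = 1:3, t = 1:3, r = 1:3)
  g$p <- edu[g$e] * eth[g$t] * reg[g$r]
  g$d <- -1.5 * g$e - 0.25 * g$t - 0.1 * g$r - 0.05 * g$t * g$r
  g
}

# Moments of the latent ability x1 = d(cell) + g(age) + z over the
# reference population: exact cell enumeration, numeric quadrature over
# age ~ Uniform(0, 6), unit-variance noise.
oracle_moments <- function() {
  cells <- oracle_cells()
  gfun <- function(a) 1.2 * a - 0.06 * a^2 + 0.0001 * a^4
  e_age <- stats::integrate(gfun, 0, 6)$value / 6
  e_age2 <- stats::integrate(function(a) gfun(a)^2, 0, 6)$value / 6
  mu_d <- sum(cells$p * cells$d)
  var_d <- sum(cells$p * (cells$d - mu_d)^2)
  list(mu = mu_d + e_age,
       sigma = sqrt(var_d + (e_age2 - e_age^2) + 1))
}

# Covariance-algebra partial correlation between the education code and
# x1 with the age polynomial controlled: education is independent of age,
# so this is cor(e, d + z) under the cell distribution.
oracle_partial_cor_education <- function() {
  cells <- oracle_cells()
  mu_e <- sum(cells$p * cells$e)
  var_e <- sum(cells$p * (cells$e - mu_e)^2)
  mu_d <- sum(cells$p * cells$d)
  var_d <- sum(cells$p * (cells$d - mu_d)^2)
  cov_ed <- sum(cells$p * (cells$e - mu_e) * (cells$d - mu_d))
  cov_ed / sqrt(var_e * (var_d + 1))
}

# Weighted mean of theta_pop for an arbitrary scenario's cell table,
# standardized by the reference moments (age part cancels between
# scenarios, so only the demographic part matters).
oracle_theta_mean <- function(edu, eth = c(.3, .4, .3),
                              reg = c(.2, .2, .6)) {
  ref <- oracle_cells()
  sc <- oracle_cells(edu, eth, reg)
  mom <- oracle_moments()
  (sum(sc$p * sc$d) - sum(ref$p * ref$d)) / mom$sigma
}

# --- reference IPF on the cross-classified array ------------------------

# Classic iterative proportional fitting on the 3-way contingency table:
# scales the full cell array against each margin in turn.  Returns the
# per-cell weight (fitted cell proportion / observed cell proportion).
oracle_ipf_cell_weights <- function(counts, targets, tol = 1e-10,
                                    max_iter = 200) {
  arr <- counts / sum(counts)
  fit <- arr
  for (it in seq_len(max_iter)) {
    for (mar in seq_along(dim(arr))) {
      cur <- apply(fit, mar, sum)
      scale <- targets[[mar]] / cur
      fit <- sweep(fit, mar, scale, `*`)
    }
    disc <- max(vapply(seq_along(dim(arr)), function(mar) {
      max(abs(apply(fit, mar, sum) - targets[[mar]]))
    }, 0))
    if (disc < tol) break
  }
  fit / arr
}

# --- shared fixtures (memoised; built once per test run) ----------------

.wcnorm_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .wcnorm_test_cache)) {
    assign(name, force(expr), envir = .wcnorm_test_cache)
  }
  get(name, envir = .wcnorm_test_cache)
}

# A small but usable reference world: 20k/cohort population, moments,
# item bank, raw scores -- enough for distributional checks.
small_reference <- function() {
  cached("small_reference", {
    spec <- scenario_cells(1)
    pop <- generate_population(spec, 20000, seed = 401)
    moments <- reference_moments(pop)
    bank <- draw_item_bank(seed = 402)
    pop$theta_pop <- standardize_ability(pop$x1, moments)
    pop$raw <- simulate_raw_scores(pop$theta_pop, bank, seed = 403)
    list(spec = spec, pop = pop, moments = moments, bank = bank)
  })
}

# One ranked scenario-1 normative sample with raked weights.
ranked_sample_fixture <- function() {
  cached("ranked_sample_fixture", {
    sr <- small_reference()
    sam <- draw_norm_sample(sr$spec, sr$moments, sr$bank, 100, seed = 404)
    w <- rake_weights(sam, margin_targets())
    sam$weight <- standardize_weights(w)
    weighted_percentile_ranks(sam)
  })
}

# A 50-row three-variable fixture with known imbalance for raking tests.
rake_fixture <- function() {
  cached("rake_fixture", {
    set.seed(405)
    data.frame(
      education = sample(1:3, 50, replace = TRUE, prob = c(.2, .3, .5)),
      ethnicity = sample(1:3, 50, replace = TRUE, prob = c(.4, .4, .2)),
      region = sample(1:3, 50, replace = TRUE, prob = c(.3, .3, .4))
    )
  })
}
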