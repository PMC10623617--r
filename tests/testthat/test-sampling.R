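# Normative samples and raking (iterative proportional fitting).

test_that("normative samples are stratified by cohort and reproducible", {
  sr <- small_reference()
  sam <- draw_norm_sample(sr$spec, sr$moments, sr$bank, 100, seed = 21)
  expect_identical(nrow(sam), 600L)
  expect_true(all(table(sam$cohort) == 100))
  expect_true(all(sam$weight == 1))
  expect_true(all(sam$raw >= 0 & sam$raw <= 31))
  sam2 <- draw_norm_sample(sr$spec, sr$moments, sr$bank, 100, seed = 21)
  expect_identical(sam, sam2)
  sam3 <- draw_norm_sample(sr$spec, sr$moments, sr$bank, 100, seed = 22)
  expect_false(identical(sam$raw, sam3$raw))
})

test_that("scenario-3 samples underrepresent high education as designed", {
  sr <- small_reference()
  spec3 <- scenario_cells(3)
  share <- vapply(1:30, function(i) {
    sam <- draw_norm_sample(spec3, sr$moments, sr$bank, 100, seed = 300 + i)
    mean(sam$education == 1)
  }, 0)
  expect_lt(abs(mean(share) - 0.20), 0.01)
})

test_that("single-margin raking reproduces the closed form", {
  d <- data.frame(education = rep(c("low", "medium", "high"), c(52, 20, 28)))
  w <- rake_weights(d, list(education = c(low = .4, medium = .2, high = .4)))
  by_cat <- vapply(split(as.numeric(w), d$education), unique, 0)
  # target / observed, normalized to the medium category
  expect_equal(by_cat[["low"]] / by_cat[["medium"]], (.4 / .52) / 1,
               tolerance = 1e-9)
  expect_equal(by_cat[["high"]] / by_cat[["medium"]], (.4 / .28) / 1,
               tolerance = 1e-9)
  expect_equal(unname(by_cat[c("low", "medium", "high")] /
                        by_cat[["medium"]]),
               c(0.7692, 1, 1.4286), tolerance = 1e-4)
})

test_that("three-variable raking matches the array-IPF oracle on a fixture", {
  d <- rake_fixture()
  targets <- list(education = c(`1` = .4, `2` = .2, `3` = .4),
                  ethnicity = c(`1` = .3, `2` = .4, `3` = .3),
                  region = c(`1` = .2, `2` = .2, `3` = .6))
  w <- rake_weights(d, targets, tol = 1e-8, max_iter = 200)
  counts <- table(factor(d$education, 1:3), factor(d$ethnicity, 1:3),
                  factor(d$region, 1:3))
  cellw <- oracle_ipf_cell_weights(
    counts, lapply(targets, unname), tol = 1e-12)
  w_oracle <- cellw[cbind(d$education, d$ethnicity, d$region)]
  # same weights up to a common scale
  expect_equal(as.numeric(w) / mean(w), w_oracle / mean(w_oracle),
               tolerance = 1e-6)
})

test_that("raking restores every weighted marginal to its target", {
  sr <- small_reference()
  sam <- draw_norm_sample(scenario_cells(2), sr$moments, sr$bank, 100,
                          seed = 23)
  targets <- margin_targets()
  w <- rake_weights(sam, targets, tol = 1e-6)
  for (v in names(targets)) {
    props <- vapply(1:3, function(c) sum(w[sam[[v]] == c]) / sum(w), 0)
    expect_lt(max(abs(props - targets[[v]])), 1e-6)
  }
  expect_true(all(w > 0))
  # post-stratification identity p_k = w_k n_k / sum(w_l n_l) per stratum
  for (v in names(targets)) {
    wk <- vapply(split(as.numeric(w), sam[[v]]), mean, 0)
    nk <- table(sam[[v]])
    expect_lt(max(abs(wk * nk / sum(wk * nk) - targets[[v]])), 1e-6)
  }
})

test_that("raking is order-invariant at convergence and reports progress", {
  d <- rake_fixture()
  t1 <- list(education = c(`1` = .4, `2` = .2, `3` = .4),
             ethnicity = c(`1` = .3, `2` = .4, `3` = .3))
  t2 <- rev(t1)
  w1 <- rake_weights(d, t1, tol = 1e-10, max_iter = 500)
  w2 <- rake_weights(d, t2, tol = 1e-10, max_iter = 500)
  expect_equal(as.numeric(w1) / mean(w1), as.numeric(w2) / mean(w2),
               tolerance = 1e-8)
  expect_gte(attr(w1, "iterations"), 1)
  expect_lt(attr(w1, "max_discrepancy"), 1e-10)
})

test_that("raking rejects unreachable targets with a named category", {
  d <- data.frame(education = rep(c("low", "high"), c(30, 20)))
  expect_error(
    rake_weights(d, list(education = c(low = .4, medium = .2, high = .4))),
    "medium")
  expect_error(
    rake_weights(d, list(education = c(low = .5, high = .5),
                         region = c(a = 1))),
    "region")
  expect_error(
    rake_weights(d, list(education = c(low = .5, medium = .5))),
    "medium")
  expect_error(rake_weights(d, list(education = c(low = .7, high = .2))),
               "sum to 1")
})

test_that("weight standardization fixes the minimum at 1, idempotently", {
  w <- standardize_weights(c(0.7692, 1, 1.4286))
  expect_equal(w, c(1, 1.3, 1.857), tolerance = 1e-3)
  expect_identical(min(w), 1)
  expect_equal(standardize_weights(w), w)
  expect_equal(standardize_weights(rep(0.25, 5)), rep(1, 5))
  expect_error(standardize_weights(c(1, 0)), "positive")
  expect_error(standardize_weights(c(1, -2)), "positive")
})

test_that("weighted proportions are invariant to weight standardization", {
  d <- rake_fixture()
  targets <- list(education = c(`1` = .4, `2` = .2, `3` = .4))
  w <- rake_weights(d, targets)
  sw <- standardize_weights(w)
  p1 <- vapply(1:3, function(c) sum(w[d$education == c]) / sum(w), 0)
  p2 <- vapply(1:3, function(c) sum(sw[d$education == c]) / sum(sw), 0)
  expect_equal(p1, p2, tolerance = 1e-12)
})
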