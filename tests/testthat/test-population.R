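# Demographic cell structure, ability surface and population generation.

test_that("cell_mean evaluates the ability surface and rejects bad input", {
  expect_equal(cell_mean(0, 3, 3, 3), -6.0)
  expect_equal(cell_mean(6, 1, 1, 1), 3.2696)
  expect_equal(cell_mean(3, 2, 2, 2), -0.8319)
  # vectorised over persons
  expect_equal(cell_mean(c(0, 6), c(3, 1), c(3, 1), c(3, 1)),
               c(-6.0, 3.2696))
  expect_error(cell_mean(7, 1, 1, 1), "age")
  expect_error(cell_mean(1, 4, 1, 1), "1, 2 or 3")
  expect_error(cell_mean(1, 1, 0, 1), "1, 2 or 3")
})

test_that("reference cell table is the exact product of its marginals", {
  tab <- scenario_cells(1)$cohort_tables[[1]]
  expect_equal(sum(tab$pct), 100, tolerance = 1e-12)
  # spot value: native (eth 3), south (reg 3), low education (edu 3)
  expect_equal(tab$pct[tab$education == 3 & tab$ethnicity == 3 &
                         tab$region == 3], 7.2)
  m <- margin_targets()
  outer3 <- 100 * m$education[tab$education] * m$ethnicity[tab$ethnicity] *
    m$region[tab$region]
  expect_equal(tab$pct, unname(outer3), tolerance = 1e-12)
})

test_that("scenarios 2-4 change only the education marginal", {
  ref <- scenario_cells(1)$cohort_tables[[1]]
  # expected education marginals by code (high, medium, low), percent
  edu_marg <- list(`2` = c(28, 20, 52), `3` = c(20, 20, 60),
                   `4` = c(30, 40, 30))
  for (s in 2:4) {
    tab <- scenario_cells(s)$cohort_tables[[1]]
    expect_equal(vapply(1:3, function(e) sum(tab$pct[tab$education == e]), 0),
                 edu_marg[[as.character(s)]], tolerance = 1e-12)
    for (v in c("ethnicity", "region")) {
      expect_equal(
        vapply(1:3, function(c) sum(tab$pct[tab[[v]] == c]), 0),
        vapply(1:3, function(c) sum(ref$pct[ref[[v]] == c]), 0),
        tolerance = 1e-12)
    }
  }
})

test_that("scenario 5 perturbs joint cells but leaves every marginal exact", {
  ref <- scenario_cells(1)$cohort_tables[[1]]
  tab <- scenario_cells(5)$cohort_tables[[1]]
  expect_gt(max(abs(tab$pct - ref$pct)), 0)
  for (v in c("education", "ethnicity", "region")) {
    expect_equal(vapply(1:3, function(c) sum(tab$pct[tab[[v]] == c]), 0),
                 vapply(1:3, function(c) sum(ref$pct[ref[[v]] == c]), 0),
                 tolerance = 1e-12)
  }
  expect_true(all(tab$pct >= 0))
  expect_error(scenario_cells(5, perturbation = 0.5), "negative")
})

test_that("scenario 6 is clustered per cohort yet pools to the reference", {
  ref <- scenario_cells(1)$cohort_tables[[1]]
  s6 <- scenario_cells(6)
  for (tab in s6$cohort_tables) {
    expect_identical(sum(tab$pct == 0), 18L)
    active <- tab$pct > 0
    expect_equal(tab$pct[active], 3 * ref$pct[active], tolerance = 1e-12)
  }
  pooled <- Reduce(`+`, lapply(s6$cohort_tables, function(t) t$pct)) / 6
  expect_equal(pooled, ref$pct, tolerance = 1e-12)
  # each block active in exactly two cohorts
  active_mat <- vapply(s6$cohort_tables, function(t) t$pct > 0,
                       logical(27))
  expect_true(all(rowSums(active_mat) == 2))
})

test_that("scenario id is validated", {
  expect_error(scenario_cells(0), "1..6")
  expect_error(scenario_cells(7), "1..6")
})

test_that("generated populations match their cell tables and construction", {
  spec <- scenario_cells(1)
  pop <- generate_population(spec, 1e5, seed = 11)
  expect_identical(nrow(pop), 6e5L)
  expect_true(all(pop$age >= 0 & pop$age < 6))
  expect_equal(pop$cohort, floor(pop$age))
  # education marginal within multinomial Monte-Carlo error (+- 0.5 pp)
  marg <- tabulate(pop$education, 3) / nrow(pop)
  expect_equal(marg, unname(margin_targets()$education), tolerance = 0.0125)
  # per-cell residuals are standard normal by construction
  resid <- pop$x1 - cell_mean(pop$age, pop$education, pop$ethnicity,
                              pop$region)
  expect_equal(mean(resid), 0, tolerance = 0.01)
  expect_equal(sd(resid), 1, tolerance = 0.01)
})

test_that("population generation is reproducible from its seed", {
  spec <- scenario_cells(3)
  p1 <- generate_population(spec, 500, seed = 7)
  p2 <- generate_population(spec, 500, seed = 7)
  p3 <- generate_population(spec, 500, seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1$x1, p3$x1))
})

test_that("reference moments match the quadrature oracle", {
  sr <- small_reference()
  mom <- sr$moments
  orc <- oracle_moments()
  expect_equal(mom$mu, orc$mu, tolerance = 0.02)
  expect_equal(mom$sigma, orc$sigma, tolerance = 0.02)
  expect_error(reference_moments(data.frame(x1 = numeric(0))), "empty")
  expect_error(reference_moments(data.frame(x1 = rep(1, 10))), "degenerate")
})

test_that("standardization uses the reference moments and flags bad sigma", {
  mom <- list(mu = 2, sigma = 4)
  expect_equal(standardize_ability(2, mom), 0)
  expect_equal(standardize_ability(c(-1, 3), list(mu = 0, sigma = 1)),
               c(-1, 3))
  expect_error(standardize_ability(1, list(mu = 0, sigma = 0)), "sigma")
  sr <- small_reference()
  expect_equal(mean(standardize_ability(sr$pop$x1, sr$moments)), 0,
               tolerance = 1e-12)
  expect_equal(sd(standardize_ability(sr$pop$x1, sr$moments)), 1,
               tolerance = 1e-12)
})

test_that("underrepresenting high education lowers the standardized mean", {
  sr <- small_reference()
  pop2 <- generate_population(scenario_cells(2), 3e4, seed = 12)
  theta <- standardize_ability(pop2$x1, sr$moments)
  expect_lt(mean(theta), 0)
  # magnitude agrees with the cell-enumeration oracle
  expect_lt(abs(mean(theta) - oracle_theta_mean(edu = c(.28, .20, .52))),
            0.02)
})

test_that("education-ability partial correlation matches covariance algebra", {
  sr <- small_reference()
  pop <- sr$pop
  agepoly <- 1.2 * pop$age - 0.06 * pop$age^2 + 0.0001 * pop$age^4
  r_emp <- cor(pop$education, pop$x1 - agepoly)
  expect_equal(r_emp, oracle_partial_cor_education(), tolerance = 0.01)
})
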