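# Weighted percentile ranks, polynomial norm models, and inversion.

test_that("weighted mid-rank percentiles follow the tie-averaged formula", {
  sam <- data.frame(cohort = 0, raw = c(10, 10, 20), weight = c(1, 1, 2))
  rk <- weighted_percentile_ranks(sam)
  expect_equal(rk$percentile, c(0.25, 0.25, 0.75))
  # unit weights reduce to RankIt (rank - 0.5) / n
  sam2 <- data.frame(cohort = 0, raw = c(5, 7), weight = c(1, 1))
  expect_equal(weighted_percentile_ranks(sam2)$percentile, c(0.25, 0.75))
  # ties with unit weights: average rank
  sam3 <- data.frame(cohort = 0, raw = c(3, 3, 3, 9), weight = rep(1, 4))
  expect_equal(weighted_percentile_ranks(sam3)$percentile,
               c(0.375, 0.375, 0.375, 0.875))
  # percentile invariant to weight rescaling
  sam4 <- sam
  sam4$weight <- sam$weight * 17.3
  expect_equal(weighted_percentile_ranks(sam4)$percentile, rk$percentile)
  expect_error(weighted_percentile_ranks(
    data.frame(cohort = 0, raw = 1:2, weight = c(1, -1))), "positive")
})

test_that("degenerate cohorts still give defined percentiles", {
  sam <- data.frame(cohort = 0, raw = rep(12, 4), weight = rep(1, 4))
  rk <- weighted_percentile_ranks(sam)
  expect_equal(rk$percentile, rep(0.5, 4))
  expect_equal(rk$location, rep(100, 4))
})

test_that("location transform is the IQ-metric inverse normal", {
  expect_equal(location_from_percentile(0.5), 100)
  expect_equal(location_from_percentile(0.841345), 115, tolerance = 0.01)
  expect_equal(location_from_percentile(0.158655), 85, tolerance = 0.01)
  expect_error(location_from_percentile(0), "strictly inside")
  expect_error(location_from_percentile(1), "strictly inside")
})

test_that("design matrix spans all exponent pairs except the constant", {
  X <- build_design_matrix(c(90, 100), c(1, 2), k = 4)
  expect_identical(ncol(X), 24L)
  X1 <- build_design_matrix(c(90, 100), c(1, 2), k = 1)
  expect_identical(colnames(X1), c("L1A0", "L0A1", "L1A1"))
  expect_equal(X1[, "L1A1"], c(90, 200))
  # zero location leaves only pure-age columns non-zero
  X0 <- build_design_matrix(0, 2, k = 2)
  nonzero <- colnames(X0)[X0[1, ] != 0]
  expect_identical(sort(nonzero), sort(c("L0A1", "L0A2")))
  expect_error(build_design_matrix(1, 1, k = 0), "at least 1")
})

test_that("term selection recovers a noise-free generating polynomial", {
  set.seed(31)
  n <- 400
  loc <- runif(n, 70, 130)
  cohort <- sample(0:5, n, replace = TRUE)
  a <- cohort + 0.5
  f_true <- function(loc, a) 5 + 0.2 * loc + 1.5 * a + 0.02 * loc * a
  rk <- data.frame(cohort = cohort, age = a, raw = f_true(loc, a),
                   weight = 1, location = loc)
  class(rk) <- c("ranked_sample", "data.frame")
  # a target this close to 1 can only be met by a model spanning the
  # generating terms exactly (the data are noise-free)
  mod <- fit_norm_model(rk, k = 4, max_terms = 6, r2_target = 1 - 1e-10)
  expect_true(mod$accepted)
  expect_equal(mod$r2, 1, tolerance = 1e-9)
  expect_true(all(c("L1A0", "L0A1") %in% mod$terms))
  expect_lte(mod$n_terms, 4)
  g <- expand.grid(loc = c(75, 100, 125), a = c(0.5, 3.5, 5.5))
  expect_equal(predict_raw(mod, g$loc, g$a), f_true(g$loc, g$a),
               tolerance = 1e-6)
})

test_that("duplicated rows and doubled weights give identical fits", {
  rk <- ranked_sample_fixture()
  half <- rk[seq_len(300), ]
  dup <- rbind(half, half)
  wtd <- half
  wtd$weight <- half$weight * 2
  # ranking unchanged: reuse the precomputed locations, only refit
  class(dup) <- class(wtd) <- c("ranked_sample", "data.frame")
  m_dup <- fit_norm_model(dup, max_terms = 6, r2_target = 0.95)
  m_wtd <- fit_norm_model(wtd, max_terms = 6, r2_target = 0.95)
  expect_identical(m_dup$terms, m_wtd$terms)
  expect_equal(unlist(m_dup$coefficients), unlist(m_wtd$coefficients),
               tolerance = 1e-8)
})

test_that("unit-weight weighted norming is bit-identical to unweighted", {
  sr <- small_reference()
  sam <- draw_norm_sample(sr$spec, sr$moments, sr$bank, 100, seed = 33)
  unw <- sam
  wtd <- sam
  wtd$weight <- rep(1, nrow(sam))    # explicit unit "raking" weights
  r1 <- weighted_percentile_ranks(unw)
  r2 <- weighted_percentile_ranks(wtd)
  expect_identical(r1$percentile, r2$percentile)
  expect_identical(r1$location, r2$location)
  m1 <- fit_norm_model(r1)
  m2 <- fit_norm_model(r2)
  expect_identical(m1$terms, m2$terms)
  expect_identical(unlist(m1$coefficients), unlist(m2$coefficients))
  g <- expand.grid(raw = c(5, 15, 25), age = c(0.8, 3.1, 5.2))
  expect_identical(
    as.numeric(predict_norm_score(m1, g$raw, g$age)),
    as.numeric(predict_norm_score(m2, g$raw, g$age)))
})

test_that("fitted models are monotone and predict their training data", {
  rk <- ranked_sample_fixture()
  mod <- fit_norm_model(rk)
  expect_true(mod$monotone)
  # predicted raw non-decreasing in location at several ages
  for (a in c(0.5, 2.5, 5.5)) {
    loc <- seq(mod$calibration$location[1], mod$calibration$location[2],
               length.out = 150)
    expect_true(all(diff(predict_raw(mod, loc, rep(a, 150))) > -1e-8))
  }
  # fitted values match a direct weighted least-squares solve
  X <- build_design_matrix(rk$location, rk$cohort + 0.5, mod$k)
  Xs <- cbind(1, X[, mod$terms, drop = FALSE])
  beta <- qr.coef(qr(sqrt(rk$weight) * Xs), sqrt(rk$weight) * rk$raw)
  pred <- as.numeric(Xs %*% beta)
  expect_equal(predict_raw(mod, rk$location, rk$cohort + 0.5), pred,
               tolerance = 1e-8)
})

test_that("single-term models evaluate as plain polynomials", {
  mod <- structure(list(terms = "L1A0",
                        coefficients = list("(Intercept)" = 0, L1A0 = 1),
                        k = 4,
                        calibration = list(location = c(40, 160),
                                           age = c(0, 6), raw = c(0, 160))),
                   class = "norm_model")
  expect_equal(predict_raw(mod, 7, 3), 7)
  expect_equal(predict_raw(mod, c(40, 100), c(1, 5)), c(40, 100))
})

test_that("norm-score inversion round-trips through the model", {
  rk <- ranked_sample_fixture()
  mod <- fit_norm_model(rk)
  loc <- seq(62, 138, by = 4)
  for (a in c(1.0, 3.5, 5.0)) {
    raw <- predict_raw(mod, loc, rep(a, length(loc)))
    back <- predict_norm_score(mod, raw, rep(a, length(loc)))
    expect_equal(as.numeric(back), loc, tolerance = 1e-3)
    expect_false(any(attr(back, "clamped")))
  }
  # raw at the model's center maps back to IQ 100
  raw100 <- predict_raw(mod, 100, 3)
  expect_equal(as.numeric(predict_norm_score(mod, raw100, 3)), 100,
               tolerance = 1e-3)
})

test_that("out-of-range raw scores are clamped and flagged", {
  rk <- ranked_sample_fixture()
  mod <- fit_norm_model(rk)
  edges <- mod$calibration$location
  top <- predict_raw(mod, edges[2], 3) + 100
  bot <- predict_raw(mod, edges[1], 3) - 100
  ns <- predict_norm_score(mod, c(bot, top), c(3, 3))
  expect_equal(as.numeric(ns), c(40, 160))
  expect_identical(attr(ns, "clamped"), c(TRUE, TRUE))
  expect_identical(attr(ns, "extrapolated"), c(TRUE, TRUE))
  # mildly out-of-range raw scores continue linearly, not wildly
  mild <- predict_raw(mod, edges[2], 3) + 0.5
  ns2 <- predict_norm_score(mod, mild, 3)
  expect_gt(as.numeric(ns2), edges[2])
  expect_lt(as.numeric(ns2), 160)
})

test_that("norm scores are non-decreasing in raw score at fixed age", {
  rk <- ranked_sample_fixture()
  mod <- fit_norm_model(rk)
  for (a in c(0.5, 2.5, 4.5)) {
    ns <- predict_norm_score(mod, 0:31, rep(a, 32))
    expect_true(all(diff(as.numeric(ns)) >= -1e-6))
  }
})
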