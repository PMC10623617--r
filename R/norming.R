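# Weighted semi-parametric continuous norming: weighted tie-averaged
# percentile ranks, inverse normal transformation to the IQ metric,
# polynomial regression of raw score on person location and age with
# weighted stepwise term selection, and numerical inversion back to norm
# scores.

#' Convert percentiles to IQ-metric person locations
#'
#' `100 + 15 * qnorm(p)`: the inverse normal transformation onto the
#' conventional IQ metric (mean 100, SD 15).
#'
#' @param p Percentiles strictly inside (0, 1).
#' @return Person locations in IQ units.
#' @export
#' @examples
#' location_from_percentile(0.5)        # 100
#' location_from_percentile(0.841345)   # ~115
location_from_percentile <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1)) {
    stop("percentiles must lie strictly inside (0, 1)", call. = FALSE)
  }
  100 + 15 * stats::qnorm(p)
}

# Weighted tie-averaged mid-rank percentiles of one vector:
# p(x) = (W_below + 0.5 * W_equal) / W_total.
.weighted_midrank <- function(raw, w) {
  o <- order(raw)
  rs <- raw[o]
  ws <- w[o]
  grp <- cumsum(!duplicated(rs))            # 1,1,2,... per tied block
  wt <- vapply(split(ws, grp), sum, 0)      # weight per distinct raw
  below <- cumsum(c(0, wt[-length(wt)]))
  p_distinct <- (below + 0.5 * wt) / sum(ws)
  p <- numeric(length(raw))
  p[o] <- p_distinct[grp]
  p
}

#' Weighted percentile ranks and person locations
#'
#' Within each one-year cohort, assigns every person the weighted
#' tie-averaged mid-rank percentile of their raw score,
#' \deqn{p = (W_{below} + 0.5\,W_{equal}) / W_{total},}
#' where the `W` are sums of post-stratification weights, and the
#' corresponding IQ-metric person location `100 + 15 * qnorm(p)`.  With
#' unit weights this reduces exactly to the RankIt mid-rank rule
#' `(mean rank - 0.5) / n` with tie averaging, so the unweighted procedure
#' is the special case of equal weights.  Percentiles are invariant to
#' rescaling of the weights.
#'
#' @param sample A `norm_sample` (columns `cohort`, `raw`, `weight`).
#' @return The sample with added columns `percentile` and `location`
#'   (class `ranked_sample`).
#' @export
weighted_percentile_ranks <- function(sample) {
  stopifnot(all(c("cohort", "raw", "weight") %in% names(sample)))
  if (any(sample$weight <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  p <- numeric(nrow(sample))
  for (j in unique(sample$cohort)) {
    ix <- which(sample$cohort == j)
    p[ix] <- .weighted_midrank(sample$raw[ix], sample$weight[ix])
  }
  sample$percentile <- p
  sample$location <- location_from_percentile(p)
  class(sample) <- unique(c("ranked_sample", class(sample)))
  sample
}

#' Polynomial design matrix in person location and age
#'
#' Builds the Taylor-polynomial candidate terms `location^i * age^j` for
#' all exponent pairs `0 <= i, j <= k` except `(0, 0)`, i.e.
#' `(k + 1)^2 - 1` columns, named `"L<i>A<j>"`.
#'
#' @param location Person locations (IQ metric).
#' @param age Ages in years.
#' @param k Maximum exponent for both location and age (default 4, giving
#'   24 candidate terms).
#' @return Numeric matrix with one row per observation.
#' @export
build_design_matrix <- function(location, age, k = 4L) {
  if (length(k) != 1L || k < 1) stop("k must be at least 1", call. = FALSE)
  k <- as.integer(k)
  grid <- expand.grid(i = 0:k, j = 0:k)
  grid <- grid[!(grid$i == 0 & grid$j == 0), , drop = FALSE]
  X <- mapply(function(i, j) location^i * age^j, grid$i, grid$j)
  X <- matrix(X, nrow = length(location),
              dimnames = list(NULL, paste0("L", grid$i, "A", grid$j)))
  attr(X, "exponents") <- cbind(i = grid$i, j = grid$j)
  X
}

# Parse "L<i>A<j>" term names back into exponent pairs.
.term_exponents <- function(terms) {
  m <- regmatches(terms, regexec("^L([0-9]+)A([0-9]+)$", terms))
  cbind(i = as.integer(vapply(m, `[`, "", 2L)),
        j = as.integer(vapply(m, `[`, "", 3L)))
}

# Coefficient matrix C[i+1, j+1] of the full bivariate polynomial,
# including the intercept at C[1, 1].
.coef_matrix <- function(model) {
  k <- model$k
  C <- matrix(0, k + 1L, k + 1L)
  C[1L, 1L] <- model$coefficients[["(Intercept)"]]
  ex <- .term_exponents(model$terms)
  for (t in seq_along(model$terms)) {
    C[ex[t, "i"] + 1L, ex[t, "j"] + 1L] <- model$coefficients[[model$terms[t]]]
  }
  C
}

# Location-polynomial coefficients b_i(age) for a vector of ages:
# predicted raw(L, a) = sum_i b_i(a) L^i.  Returns length(age) x (k+1).
.loc_poly_coefs <- function(model, age) {
  k <- model$k
  A <- outer(age, 0:k, `^`)
  A %*% t(.coef_matrix(model))
}

# Monotonicity audit: is predicted raw non-decreasing in location at every
# grid age over the given ranges?
.is_monotone <- function(model, loc_range, age_range,
                         n_loc = 200L, n_age = 60L) {
  loc <- seq(loc_range[1L], loc_range[2L], length.out = n_loc)
  age <- seq(age_range[1L], age_range[2L], length.out = n_age)
  B <- .loc_poly_coefs(model, age)              # n_age x (k+1)
  L <- outer(loc, 0:model$k, `^`)               # n_loc x (k+1)
  F <- L %*% t(B)                               # n_loc x n_age
  slack <- 1e-8 * max(abs(F))
  all(diff(F) >= -slack)
}

.wls_rss <- function(X, y, w) {
  fit <- stats::lm.wfit(X, y, w)
  sum(w * fit$residuals^2)
}

#' Fit a continuous norm model
#'
#' Regresses raw score on a polynomial in person location and age by
#' weighted least squares, selecting a best subset of the
#' `(k + 1)^2 - 1` candidate terms of [build_design_matrix()]: at each
#' size `m = 1..max_terms` a stepwise-with-replacement search minimises
#' the weighted residual sum of squares, and the final model is the
#' smallest size whose
#' adjusted R-squared reaches `r2_target` *and* whose predicted raw score
#' is non-decreasing in location at every age on a 200 x 60 calibration
#' grid.  If no size qualifies, the monotone candidate with the highest
#' adjusted R-squared is returned and flagged as best-available.
#'
#' The raking weights stored in the sample are used both here and in the
#' preceding ranking step (weighted continuous norming, WCN); with unit
#' weights the procedure is plain semi-parametric continuous norming (SCN)
#' and the fit equals the unweighted one exactly.
#'
#' By default the age predictor is the cohort midpoint (`cohort + 0.5`)
#' rather than exact age, because person locations are estimated per
#' cohort and therefore carry no within-cohort age information; predictions
#' at arbitrary continuous ages interpolate across cohorts.
#'
#' @param ranked A `ranked_sample` from [weighted_percentile_ranks()].
#' @param k Maximum exponent of location and age (default 4).
#' @param max_terms Maximum number of polynomial terms (default 12).
#' @param r2_target Adjusted R-squared acceptance threshold (default
#'   0.99).
#' @param age Either `"midpoint"` (default) or `"continuous"`.
#' @param selection `"replacement"` (default): forward stepwise search
#'   refined by swapping single terms while the weighted residual sum of
#'   squares improves, a close approximation to exact best-subset
#'   selection per size; `"forward"` for the plain (cheaper) stepwise
#'   search.
#' @return A `norm_model`: list with `terms`, `coefficients` (including
#'   `(Intercept)`), `k`, `r2`, `adj_r2`, `n_terms`, `accepted`,
#'   `monotone`, `weighted`, and `calibration` ranges of location, age and
#'   raw score.
#' @export
fit_norm_model <- function(ranked, k = 4L, max_terms = 12L, r2_target = 0.99,
                           age = c("midpoint", "continuous"),
                           selection = c("replacement", "forward")) {
  stopifnot(inherits(ranked, "ranked_sample"))
  age <- match.arg(age)
  selection <- match.arg(selection)
  n <- nrow(ranked)
  if (n < max_terms + 2L) {
    stop("need at least max_terms + 2 observations", call. = FALSE)
  }
  a <- if (age == "midpoint") ranked$cohort + 0.5 else ranked$age
  y <- ranked$raw
  w <- ranked$weight
  X <- build_design_matrix(ranked$location, a, k)
  cand <- colnames(X)
  loc_range <- range(ranked$location)
  age_range <- range(a)
  if (diff(age_range) == 0) age_range <- age_range + c(-0.5, 0.5)

  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  rss_of <- function(terms) {
    .wls_rss(cbind(1, X[, terms, drop = FALSE]), y, w)
  }
  sel <- character(0L)
  path <- vector("list", max_terms)
  for (m in seq_len(max_terms)) {
    remaining <- setdiff(cand, sel)
    rss <- vapply(remaining, function(term) rss_of(c(sel, term)), 0)
    sel <- c(sel, remaining[which.min(rss)])
    cur <- min(rss)
    if (selection == "replacement") {
      # sequential replacement: swap single terms while the weighted RSS
      # improves, a close approximation to exact best subset per size
      repeat {
        improved <- FALSE
        for (i in seq_along(sel)) {
          rem2 <- setdiff(cand, sel)
          rss2 <- vapply(rem2, function(term) rss_of(c(sel[-i], term)), 0)
          if (min(rss2) < cur - 1e-10 * tss) {
            sel[i] <- rem2[which.min(rss2)]
            cur <- min(rss2)
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    r2 <- 1 - cur / tss
    path[[m]] <- list(terms = sel, rss = cur, r2 = r2,
                      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - m - 1))
  }

  make_model <- function(terms) {
    fit <- stats::lm.wfit(cbind("(Intercept)" = 1,
                                X[, terms, drop = FALSE]), y, w)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    structure(list(terms = terms, coefficients = as.list(cf), k = k,
                   calibration = list(location = loc_range, age = age_range,
                                      raw = range(y))),
              class = "norm_model")
  }

  chosen <- NULL
  accepted <- FALSE
  for (m in seq_len(max_terms)) {
    if (path[[m]]$adj_r2 >= r2_target) {
      mod <- make_model(path[[m]]$terms)
      if (.is_monotone(mod, loc_range, age_range)) {
        chosen <- m
        accepted <- TRUE
        break
      }
    }
  }
  if (is.null(chosen)) {
    # no size reaches the target while monotone: best monotone fallback
    best_adj <- -Inf
    for (m in seq_len(max_terms)) {
      mod <- make_model(path[[m]]$terms)
      if (.is_monotone(mod, loc_range, age_range) &&
          path[[m]]$adj_r2 > best_adj) {
        best_adj <- path[[m]]$adj_r2
        chosen <- m
      }
    }
    if (is.null(chosen)) {
      stop("no monotone norm model found at any size; consider a lower k ",
           "or a larger sample", call. = FALSE)
    }
  }
  model <- make_model(path[[chosen]]$terms)
  model$r2 <- path[[chosen]]$r2
  model$adj_r2 <- path[[chosen]]$adj_r2
  model$n_terms <- chosen
  model$accepted <- accepted
  model$monotone <- TRUE
  model$weighted <- !isTRUE(all(w == w[1L]))
  model
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf(
    "Continuous norm model (%s): %d term(s), R2 = %.5f, adj. R2 = %.5f%s\n",
    if (isTRUE(x$weighted)) "weighted" else "unweighted",
    x$n_terms, x$r2, x$adj_r2,
    if (isTRUE(x$accepted)) "" else " [best available]"))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat(sprintf("  calibration: location [%.1f, %.1f], age [%.2f, %.2f]\n",
              x$calibration$location[1L], x$calibration$location[2L],
              x$calibration$age[1L], x$calibration$age[2L]))
  invisible(x)
}

#' Predict raw scores from a norm model
#'
#' Evaluates the fitted polynomial at given person locations and ages.
#' No clamping is applied.
#'
#' @param model A `norm_model`.
#' @param location Person locations (IQ metric), vectorised.
#' @param age Ages in years, vectorised (recycled against `location`).
#' @return Predicted raw scores (numeric, not rounded).
#' @export
predict_raw <- function(model, location, age) {
  stopifnot(inherits(model, "norm_model"))
  nn <- max(length(location), length(age))
  location <- rep_len(location, nn)
  age <- rep_len(age, nn)
  B <- .loc_poly_coefs(model, age)
  L <- outer(location, 0:model$k, `^`)
  rowSums(B * L)
}

#' Norm scores from raw scores (model inversion)
#'
#' Solves `predict_raw(model, location, age) = raw` for the person
#' location by bisection to within `tol` IQ points.  The polynomial is
#' trusted only over the location range it was calibrated on: outside
#' that range the prediction function is continued *linearly* with the
#' slope at the calibration boundary (polynomial extrapolation of a
#' quartic is meaningless there and occasionally wild), up to the limits
#' of `interval` (default IQ 40-160).  Raw scores below or above the
#' attainable prediction range at the person's age are clamped to the
#' interval endpoint; both extrapolated and clamped scores are flagged
#' via the `"extrapolated"` and `"clamped"` attributes.  A coarse grid
#' with a running maximum is used to bracket the root, which keeps the
#' inversion well-behaved when the polynomial is only monotone over the
#' calibration range.
#'
#' @param model A `norm_model`.
#' @param raw Raw scores, vectorised.
#' @param age Ages in years, vectorised (recycled).
#' @param interval Overall search interval for the location (default
#'   `c(40, 160)`).
#' @param tol Bisection tolerance in IQ points (default `1e-4`).
#' @return Numeric vector of norm scores (IQ metric) with logical
#'   attributes `"clamped"` (raw outside the attainable range) and
#'   `"extrapolated"` (norm score beyond the calibrated location range).
#' @export
predict_norm_score <- function(model, raw, age, interval = c(40, 160),
                               tol = 1e-4) {
  stopifnot(inherits(model, "norm_model"))
  if (length(interval) != 2L || interval[1L] >= interval[2L]) {
    stop("interval must be an increasing pair", call. = FALSE)
  }
  nn <- max(length(raw), length(age))
  raw <- rep_len(as.numeric(raw), nn)
  age <- rep_len(age, nn)
  kk <- model$k
  B <- .loc_poly_coefs(model, age)              # nn x (k+1)
  cal <- model$calibration$location
  cal_lo <- max(interval[1L], cal[1L])
  cal_hi <- min(interval[2L], cal[2L])
  pow <- function(loc) outer(loc, 0:kk, `^`)
  dpow <- function(loc) outer(loc, 0:kk, function(l, i) {
    ifelse(i == 0, 0, i * l^(pmax(i - 1, 0)))
  })
  f_lo <- rowSums(B * pow(rep(cal_lo, nn)))     # value at calibration edges
  f_hi <- rowSums(B * pow(rep(cal_hi, nn)))
  s_lo <- pmax(rowSums(B * dpow(rep(cal_lo, nn))), 1e-8)
  s_hi <- pmax(rowSums(B * dpow(rep(cal_hi, nn))), 1e-8)

  out <- numeric(nn)
  extrapolated <- logical(nn)
  clamp_lo <- logical(nn)
  clamp_hi <- logical(nn)

  # linear continuation below / above the calibrated location range
  lo_side <- raw <= f_lo
  hi_side <- raw >= f_hi
  if (any(lo_side)) {
    val <- cal_lo + (raw[lo_side] - f_lo[lo_side]) / s_lo[lo_side]
    clamp_lo[lo_side] <- val < interval[1L]
    out[lo_side] <- pmax(val, interval[1L])
    extrapolated[lo_side] <- TRUE
  }
  if (any(hi_side)) {
    val <- cal_hi + (raw[hi_side] - f_hi[hi_side]) / s_hi[hi_side]
    clamp_hi[hi_side] <- val > interval[2L]
    out[hi_side] <- pmin(val, interval[2L])
    extrapolated[hi_side] <- TRUE
  }

  inner <- !(lo_side | hi_side)
  if (any(inner)) {
    # bracket on a unit-step grid over the calibrated range with a
    # running maximum (monotone envelope), then bisect
    grid <- seq(cal_lo, cal_hi, by = 1)
    if (grid[length(grid)] < cal_hi) grid <- c(grid, cal_hi)
    Bi <- B[inner, , drop = FALSE]
    ri <- raw[inner]
    Fg <- Bi %*% t(pow(grid))
    for (g in seq_along(grid)[-1L]) {
      Fg[, g] <- pmax(Fg[, g], Fg[, g - 1L])
    }
    below <- pmax(pmin(rowSums(Fg < ri), length(grid) - 1L), 1L)
    lo <- grid[below]
    hi <- grid[below + 1L]
    n_iter <- ceiling(log2(max(hi - lo) / tol))
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      fm <- rowSums(Bi * pow(mid))
      take_lo <- fm < ri
      lo <- ifelse(take_lo, mid, lo)
      hi <- ifelse(take_lo, hi, mid)
    }
    out[inner] <- (lo + hi) / 2
  }
  attr(out, "clamped") <- clamp_lo | clamp_hi
  attr(out, "extrapolated") <- extrapolated
  out
}
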