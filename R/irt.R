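# 1-PL (Rasch) test simulator: item bank, response probabilities, raw scores.

#' Draw a bank of item difficulties
#'
#' Item difficulties are independent Uniform(lo, hi) draws on the latent
#' ability scale.  The simulated test of the study design has 31 items with
#' difficulties on \[-3, 3\], covering a wide ability range.  One bank is
#' drawn per experiment and shared by every population, replicate and the
#' benchmark-norm computation, so that norming methods are compared on the
#' same test.
#'
#' @param n_items Number of items (default 31).
#' @param lo,hi Difficulty bounds (default -3, 3); `lo < hi` required.
#' @param seed Integer seed.
#' @return An `item_bank` object: list with `difficulties`, `lo`, `hi`,
#'   `seed`.
#' @export
#' @examples
#' bank <- draw_item_bank(seed = 42)
#' range(bank$difficulties)
draw_item_bank <- function(n_items = 31L, lo = -3, hi = 3, seed) {
  if (length(n_items) != 1L || n_items < 1) {
    stop("n_items must be a positive count", call. = FALSE)
  }
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("invalid difficulty bounds: need lo < hi", call. = FALSE)
  }
  set.seed(as.integer(seed))
  structure(list(difficulties = stats::runif(as.integer(n_items), lo, hi),
                 lo = lo, hi = hi, seed = as.integer(seed)),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  d <- x$difficulties
  cat(sprintf(
    "1-PL item bank: %d items on [%g, %g] (M = %.2f, SD = %.2f), seed %d\n",
    length(d), x$lo, x$hi, mean(d), stats::sd(d), x$seed))
  invisible(x)
}

#' 1-PL response probability
#'
#' Probability that a person with standardized ability `theta` solves an
#' item with difficulty `delta` under the one-parameter logistic model,
#' `exp(theta - delta) / (1 + exp(theta - delta))`.  Evaluated as
#' `plogis(theta - delta)`, which is numerically stable for large
#' `|theta - delta|`.
#'
#' @param theta Standardized person ability (vectorised).
#' @param delta Item difficulty (vectorised, recycled).
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' response_probability(0, 0)    # 0.5
#' response_probability(1, 0)    # 0.731...
response_probability <- function(theta, delta) {
  stats::plogis(theta - delta)
}

#' Simulate raw test scores
#'
#' For every person and item, a Uniform(0, 1) number is drawn and the item
#' is scored 1 when the 1-PL success probability exceeds it; item scores
#' are summed into an integer raw score in `0..n_items`.  Draws proceed
#' item by item over the person vector, so results are reproducible from
#' the seed.
#'
#' @param thetas Numeric vector of standardized abilities.
#' @param bank An `item_bank`.
#' @param seed Integer seed.
#' @return Integer vector of raw scores, same length as `thetas`.
#' @export
simulate_raw_scores <- function(thetas, bank, seed) {
  stopifnot(inherits(bank, "item_bank"))
  delta <- bank$difficulties
  if (length(delta) == 0L) stop("item bank is empty", call. = FALSE)
  set.seed(as.integer(seed))
  raw <- integer(length(thetas))
  for (d in delta) {
    p <- stats::plogis(thetas - d)
    raw <- raw + (stats::runif(length(thetas)) < p)
  }
  as.integer(raw)
}
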