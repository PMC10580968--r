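# Internal helpers shared across modules.

#' Nearest-rank quantile
#'
#' The k-th smallest value with k = ceiling(q * n), the classic nearest-rank
#' percentile. Used for all percentile-based classification cuts so that
#' counts are reproducible across platforms.
#'
#' @param x numeric vector (NAs removed).
#' @param q quantile in (0, 1].
#' @return a single value of `x`.
#' @keywords internal
nearest_rank_quantile <- function(x, q) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) stop("no non-missing values")
  k <- min(length(x), max(1L, as.integer(ceiling(q * length(x)))))
  x[k]
}

# Wilson score interval for a binomial proportion; z defaults to the 95% level.
wilson_interval <- function(p, n, z = qnorm(0.975)) {
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

# Percentage of a count over a total, rounded to one decimal (the convention
# used when reporting trait-group sizes).
fraction_pct <- function(k, n) round(100 * k / n, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
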