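#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a base seed and a stream label.
# Splitmix-style integer mixing keeps independent substreams for
# per-participant / per-day / per-operation randomness while staying
# below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }))
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    h <- (h * 48271 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler for the normal distribution truncated to
#' `[lower, upper]`. With `sd = 0` the distribution is degenerate at
#' `mean` (clipped to the bounds).
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (sd < 0) stopf("sd must be nonnegative, got %g", sd)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Distribution function of a truncated normal
#'
#' @param q quantiles.
#' @inheritParams rtnorm
#' @return cumulative probabilities.
#' @export
ptnorm <- function(q, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  p <- (stats::pnorm(q, mean, sd) - plo) / (phi - plo)
  pmin(pmax(p, 0), 1)
}

# run-length helper returning start/end indices and values
runs_of <- function(x) {
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, length = r$lengths,
             value = r$values, stringsAsFactors = FALSE)
}
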