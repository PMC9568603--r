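#' Truncated normal sampling by inverse CDF
#'
#' Exact (rejection-free) truncated-normal sampler used by the synthetic-data
#' generator for all SD-bearing planted quantities.
#'
#' @param n Number of draws.
#' @param mean,sd Latent normal location and scale.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("'sd' must be positive")
  if (lower >= upper) stop("'lower' must be below 'upper'")
  plo <- stats::pnorm((lower - mean) / sd)
  phi <- stats::pnorm((upper - mean) / sd)
  if (phi - plo < 1e-12) stop("truncation window has negligible mass")
  u <- stats::runif(n, plo, phi)
  mean + sd * stats::qnorm(u)
}

# Mean of a normal(mu, sd) truncated to [a, b].
tnorm_mean <- function(mu, sd, a = -Inf, b = Inf) {
  za <- (a - mu) / sd
  zb <- (b - mu) / sd
  mass <- stats::pnorm(zb) - stats::pnorm(za)
  mu + sd * (stats::dnorm(za) - stats::dnorm(zb)) / mass
}

#' Mean-matched truncated normal draws
#'
#' Draws from a normal truncated to `[lower, upper]` whose *realized*
#' (truncated) mean equals `mean`: the latent location is solved for, with the
#' latent scale fixed at `sd`. Reported summary statistics describe measured,
#' range-limited data, so planting them as a naive truncated normal would bias
#' every recovered mean upward (or downward); matching the truncated mean to
#' the reported mean keeps the planted population centered on the reported
#' value.
#'
#' @inheritParams rtnorm
#' @return Numeric vector of length `n`.
#' @export
rtnorm_matched <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (mean <= lower || mean >= upper) {
    stop("target mean must lie strictly inside the truncation window")
  }
  f <- function(mu) tnorm_mean(mu, sd, lower, upper) - mean
  lo <- mean - 6 * sd
  hi <- mean + 6 * sd
  # tnorm_mean is increasing in mu; widen until the root is bracketed
  while (f(lo) > 0 && is.finite(lo)) lo <- lo - 4 * sd
  while (f(hi) < 0 && is.finite(hi)) hi <- hi + 4 * sd
  mu0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  rtnorm(n, mu0, sd, lower, upper)
}

#' Derive a per-track seed from a master seed
#'
#' One seeded stream per track, derived by stable integer hashing from
#' `(master seed, track id)`, keeps multi-track experiments reproducible and
#' order-independent. The result is always in `[1, 2^31 - 2]`.
#'
#' @param master Master seed (integer).
#' @param id Track or stream id (integer).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, id) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master) %% m) * 48271 %% m
  h <- (h + as.numeric(id) * 16807) %% m
  h <- (h * 69621) %% m
  as.integer(h %% (m - 1)) + 1L
}
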