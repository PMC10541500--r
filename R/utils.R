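#' Derive a deterministic sub-stream seed
#'
#' All generators draw from sub-streams derived from one global seed so that
#' each dataset kind can be regenerated independently while the global seed
#' fully determines every output. Offsets are fixed per generator.
#'
#' @param seed integer global seed.
#' @param offset integer offset identifying the sub-stream.
#' @return an integer seed below 2^31.
#' @keywords internal
substream <- function(seed, offset) {
  (abs(as.integer(seed)) %% 2147400000L) + as.integer(offset)
}

#' Beta-binomial random draws
#'
#' Overdispersed binomial counts: the success probability of each draw is
#' Beta(mu * theta, (1 - mu) * theta), so `theta` (the Beta precision
#' alpha + beta) controls overdispersion; the intraclass correlation is
#' 1 / (1 + theta).
#'
#' @param n number of draws.
#' @param size vector of trial counts.
#' @param mu mean success probability, in (0, 1).
#' @param theta precision (> 0); smaller values give heavier overdispersion.
#' @return integer vector of counts, elementwise <= `size`.
#' @export
rbetabinom <- function(n, size, mu, theta) {
  stopifnot(all(theta > 0))
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  p <- stats::rbeta(n, mu * theta, (1 - mu) * theta)
  stats::rbinom(n, size, p)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorised standardisation to mean 0 / SD 1 that tolerates zero variance
# (returns zeros), used when turning planned design covariates into the
# z-scale on which generating coefficients are defined
zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
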