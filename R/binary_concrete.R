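#' Binary concrete (relaxed Bernoulli) distribution parameters
#'
#' The binary concrete distribution is a continuous relaxation of the
#' Bernoulli on the open interval (0, 1). It is parameterized by a
#' probability map `probs` (the probability that a draw exceeds 1/2) and a
#' temperature `temperature` controlling how tightly draws concentrate near
#' {0, 1}. As the temperature approaches zero the distribution converges to
#' Bernoulli(`probs`).
#'
#' @param probs Numeric vector with entries strictly inside (0, 1), one per
#'   variant.
#' @param temperature Positive scalar relaxation temperature.
#' @return An object of class `"bc_params"`.
#' @examples
#' par <- bc_params(c(0.1, 0.9), temperature = 0.5)
#' bc_sample(par, uniforms = c(0.3, 0.7))
#' @export
bc_params <- function(probs, temperature) {
  probs <- as.numeric(probs)
  if (length(probs) < 1L || anyNA(probs) || any(probs <= 0) || any(probs >= 1)) {
    stop("`probs` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("`temperature` must be a positive scalar")
  }
  structure(list(probs = probs, temperature = as.numeric(temperature)),
            class = "bc_params")
}

#' Sample from the binary concrete distribution
#'
#' Draws are a smooth deterministic function of the parameters given the
#' exogenous uniform variates (the reparameterization trick):
#' `c_i = sigmoid((logit(u_i) + logit(p_i)) / temperature)`. Supplying the
#' uniforms explicitly keeps all randomness under the caller's seeded
#' generator and makes the map differentiable in `probs`.
#'
#' At very small temperatures draws saturate to exactly 0 or 1 in floating
#' point; that is the intended Bernoulli limit.
#'
#' @param params A [bc_params()] object.
#' @param uniforms Numeric vector, same length as `params$probs`, with
#'   entries strictly inside (0, 1).
#' @return Numeric vector of relaxed causal indicators in \[0, 1\].
#' @export
bc_sample <- function(params, uniforms) {
  stopifnot(inherits(params, "bc_params"))
  uniforms <- as.numeric(uniforms)
  if (length(uniforms) != length(params$probs)) {
    stop("`uniforms` must have one entry per probability")
  }
  if (anyNA(uniforms) || any(uniforms <= 0) || any(uniforms >= 1)) {
    stop("`uniforms` must lie strictly inside (0, 1): logit undefined at 0/1")
  }
  stats::plogis((stats::qlogis(uniforms) + stats::qlogis(params$probs)) /
                  params$temperature)
}

#' Element-wise log density of the binary concrete distribution
#'
#' Evaluated in log space for overflow safety:
#' `log q = log(lambda) + log p + log(1-p) - (lambda+1) (log c + log(1-c))
#'   - 2 logsumexp(log p - lambda log c, log(1-p) - lambda log(1-c))`.
#'
#' @param x Numeric vector of draws, strictly inside (0, 1).
#' @param params A [bc_params()] object.
#' @return Numeric vector of per-element log densities.
#' @export
bc_log_density <- function(x, params) {
  stopifnot(inherits(params, "bc_params"))
  x <- as.numeric(x)
  if (length(x) != length(params$probs)) {
    stop("`x` must have one entry per probability")
  }
  if (anyNA(x) || any(x <= 0) || any(x >= 1)) {
    stop("density diverges at the boundary: `x` must lie strictly inside (0, 1)")
  }
  p <- params$probs
  lam <- params$temperature
  lc <- log(x)
  l1c <- log1p(-x)
  a <- log(p) - lam * lc
  b <- log1p(-p) - lam * l1c
  hi <- pmax(a, b)
  lse <- hi + log1p(exp(pmin(a, b) - hi))
  log(lam) + log(p) + log1p(-p) - (lam + 1) * (lc + l1c) - 2 * lse
}

#' KL divergence between Bernoulli vectors (small-temperature limit)
#'
#' In the small-temperature regime the binary concrete proposal behaves like
#' a Bernoulli, and the KL divergence from a uniform Bernoulli prior with
#' per-variant probability `p0` reduces to the sum of element-wise Bernoulli
#' KL terms. This is the sparsity regularizer of the variational loss.
#'
#' @param probs Numeric vector strictly inside (0, 1).
#' @param p0 Scalar prior inclusion probability, strictly inside (0, 1).
#' @return Nonnegative scalar; zero iff `probs` is constant at `p0`.
#' @export
kl_bernoulli <- function(probs, p0) {
  probs <- as.numeric(probs)
  if (anyNA(probs) || any(probs <= 0) || any(probs >= 1)) {
    stop("`probs` must lie strictly inside (0, 1)")
  }
  if (length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1) {
    stop("`p0` must be a scalar strictly inside (0, 1)")
  }
  sum(probs * (log(probs) - log(p0)) +
        (1 - probs) * (log1p(-probs) - log1p(-p0)))
}

#' Linear temperature annealing schedule
#'
#' During training the proposal temperature is lowered at a fixed constant
#' rate from `lambda_start` to a small nonzero `lambda_end` (default 0.01),
#' so that early steps explore soft relaxed samples and late steps approach
#' the Bernoulli limit.
#'
#' @param lambda_start Positive starting temperature.
#' @param lambda_end Positive final temperature, at most `lambda_start`.
#' @param total_steps Positive integer count of training steps.
#' @return An object of class `"anneal_schedule"`.
#' @export
anneal_schedule <- function(lambda_start = 0.5, lambda_end = 0.01,
                            total_steps = 1000L) {
  if (lambda_start <= 0 || lambda_end <= 0) stop("temperatures must be positive")
  if (lambda_end > lambda_start) stop("`lambda_end` must not exceed `lambda_start`")
  total_steps <- as.integer(total_steps)
  if (total_steps < 1L) stop("`total_steps` must be a positive integer")
  structure(list(lambda_start = lambda_start, lambda_end = lambda_end,
                 total_steps = total_steps),
            class = "anneal_schedule")
}

#' Temperature at a given training step
#'
#' Linear interpolation between the endpoints; steps beyond the horizon are
#' clamped to `lambda_end`.
#'
#' @param schedule An [anneal_schedule()] object.
#' @param step Nonnegative integer step index (0 = before the first update).
#' @return Positive scalar temperature.
#' @export
temperature_at <- function(schedule, step) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  if (step < 0) stop("`step` must be nonnegative")
  frac <- min(step / schedule$total_steps, 1)
  schedule$lambda_start + frac * (schedule$lambda_end - schedule$lambda_start)
}
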