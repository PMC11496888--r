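# Shared fixture builders. Everything is generated in code; no stored data.

# Random positive-definite correlation matrix of size m.
random_corr <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- matrix(rnorm(m * (m + 2L)), m + 2L, m)
  S <- crossprod(F)
  d <- sqrt(diag(S))
  S / (d %o% d)
}

# Small synthetic locus with arbitrary (non-simulated) z-scores.
toy_summary <- function(m = 3L, seed = 1L, n = 1000L, z = NULL) {
  set.seed(seed)
  ld <- random_corr(m)
  if (is.null(z)) z <- rnorm(m)
  summary_input(z = z, ld = ld, n_samples = n)
}

# Dense multivariate normal log density at x ~ N(0, S), written directly so
# likelihood tests have an independent evaluation path.
ref_mvn_logpdf <- function(x, S) {
  R <- chol(S)
  u <- backsolve(R, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(u^2))
}

# The model scale of the z-scores when the studentization adjustment is on.
ref_effective_z <- function(z, n) sqrt(n) * z / sqrt(max(n - 2, 1) + z^2)

# Brute-force posterior over an explicit list of configuration supports:
# direct summation of likelihood x prior, no package posterior code.
ref_config_posterior <- function(supports, z, ld, hyper, n) {
  m <- length(z)
  A <- ld
  diag(A) <- diag(A) + hyper$ridge
  p0 <- if (is.null(hyper$p0)) 1 / m else hyper$p0
  zz <- if (isTRUE(hyper$adjust_z)) ref_effective_z(z, n) else z
  ns2 <- if (is.null(hyper$nsigma2)) max(max(zz^2) - 1, 1) else hyper$nsigma2
  lw <- vapply(supports, function(sup) {
    cv <- numeric(m)
    cv[sup] <- 1
    S <- A + A %*% (ns2 * cv * A)
    ref_mvn_logpdf(zz, (S + t(S)) / 2) +
      length(sup) * log(p0) + (m - length(sup)) * log(1 - p0)
  }, numeric(1))
  w <- exp(lw - max(lw))
  w / sum(w)
}

# Evaluate a scalar-parameter binary concrete log density at many points.
bc_log_density_vec <- function(x, par) {
  bc_log_density(x, bc_params(rep(par$probs[1], length(x)), par$temperature))
}

# Total mass of the binary concrete density. The density has integrable
# c^(lambda-1) singularities at both endpoints when lambda < 1, so quadrature
# runs on the logistic scale c = plogis(t).
# Total mass via the substitution w = c^lambda on each half (the density has
# c^(lambda-1) boundary singularities; on the w scale the integrand is
# bounded, with analytic limit (1-p)/p at w -> 0). The upper half follows by
# the symmetry q(c; p) = q(1 - c; 1 - p).
bc_total_mass <- function(par) {
  half <- function(p, lam) {
    integrate(function(w) {
      vapply(w, function(wi) {
        if (wi <= 0) return((1 - p) / p)
        ci <- exp(log(wi) / lam)
        if (ci < 1e-300) return((1 - p) / p)
        exp(bc_log_density(ci, bc_params(p, lam)) +
              (1 / lam - 1) * log(wi) - log(lam))
      }, numeric(1))
    }, 0, 0.5^lam, rel.tol = 1e-10)$value
  }
  p <- par$probs[1]
  half(p, par$temperature) + half(1 - p, par$temperature)
}

bc_bin_mass <- function(par, a, b) {
  lam <- par$temperature  # c = plogis(s / lambda) gives O(1) exponential tails
  integrate(function(s) {
    c_ <- plogis(s / lam)
    out <- numeric(length(c_))
    inside <- c_ > 0 & c_ < 1  # integrand -> 0 at saturated tails
    if (any(inside)) {
      out[inside] <- exp(bc_log_density_vec(c_[inside], par)) *
        c_[inside] * (1 - c_[inside]) / lam
    }
    out
  }, if (a <= 0) -Inf else lam * qlogis(a), if (b >= 1) Inf else lam * qlogis(b),
  rel.tol = 1e-9, subdivisions = 500L)$value
}

all_subsets <- function(m) {
  out <- list(integer(0))
  for (k in seq_len(m)) {
    out <- c(out, combn(m, k, simplify = FALSE))
  }
  out
}
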