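#' Per-locus GWAS summary input
#'
#' Bundles the observational input to fine-mapping: per-variant z-scores, the
#' LD (Pearson correlation) matrix of the locus, and the GWAS sample size.
#'
#' @param z Numeric vector of GWAS z-scores, length m.
#' @param ld m x m LD correlation matrix: symmetric within 1e-8 with unit
#'   diagonal within 1e-6.
#' @param n_samples Positive integer GWAS sample size.
#' @param variant_ids Optional character vector of m variant identifiers.
#' @return An object of class `"summary_input"`.
#' @export
summary_input <- function(z, ld, n_samples, variant_ids = NULL) {
  z <- as.numeric(z)
  ld <- as.matrix(ld)
  m <- length(z)
  if (anyNA(z) || any(!is.finite(z))) stop("`z` must be finite")
  if (nrow(ld) != m || ncol(ld) != m) {
    stop(sprintf("dimension mismatch: length(z) = %d but ld is %d x %d",
                 m, nrow(ld), ncol(ld)))
  }
  if (max(abs(ld - t(ld))) > 1e-8) stop("`ld` must be symmetric within 1e-8")
  if (max(abs(diag(ld) - 1)) > 1e-6) stop("`ld` diagonal must be 1 within 1e-6")
  if (!is.null(variant_ids)) {
    variant_ids <- as.character(variant_ids)
    if (length(variant_ids) != m) stop("`variant_ids` must have length m")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("`n_samples` must be positive")
  structure(list(z = z, ld = ld, n_samples = n_samples,
                 variant_ids = variant_ids, m = m),
            class = "summary_input")
}

#' @export
print.summary_input <- function(x, ...) {
  cat(sprintf("summary_input: %d variants, n = %d, max |z| = %.2f\n",
              x$m, x$n_samples, max(abs(x$z))))
  invisible(x)
}

#' Model hyperparameters
#'
#' Tunables of the marginal z-score likelihood and of configuration
#' harvesting. The likelihood depends on the prior effect-size variance only
#' through the product n * sigma^2, so that product is the exposed knob.
#'
#' @param nsigma2 Prior variance of a causal effect on the z-score scale
#'   (the product n * sigma^2, the only combination the likelihood depends
#'   on). `NULL` (default) estimates it per locus by the moment relation
#'   `max(max(z^2) - 1, 1)`: under the model the strongest signal's marginal
#'   variance is `1 + n sigma^2` when that variant is causal. A fixed
#'   positive value may be supplied instead.
#' @param ridge Nonnegative diagonal regularization added to the LD matrix
#'   before any solve (empirical LD is often rank-deficient). Default 1e-4.
#' @param gamma Binarization threshold in (0,1) used to harvest causal
#'   configurations from relaxed samples. Default 0.1.
#' @param sample_threshold Support threshold in (0,1): sample entries below
#'   it are zeroed before the likelihood. Default 0.01.
#' @param prune_size Maximum support size retained per sample. Default 50.
#' @param num_mc_samples Monte Carlo sample count L per training step.
#'   Default 16.
#' @param p0 Scalar prior inclusion probability in (0,1); `NULL` (default)
#'   means 1/m, resolved against the locus at fit time.
#' @param adjust_z Logical, default `TRUE`: evaluate the likelihood on
#'   effective z-scores `sqrt(n) * z / sqrt(n - 2 + z^2)` (the sqrt(n)-scaled
#'   marginal genotype-phenotype correlation). Per-variant studentization
#'   inflates raw z at variants with large marginal R^2 by
#'   `1/sqrt(1 - R^2)`, which violates the cross-variant consistency the
#'   LD-based multivariate-normal model assumes and manufactures spurious
#'   inclusions at strong LD partners; the standardized-effect scale removes
#'   that distortion (the same conversion summary-statistic tools such as
#'   susieR apply when the sample size is known). Set `FALSE` to use raw
#'   z-scores.
#' @return An object of class `"model_hyper"`.
#' @export
model_hyper <- function(nsigma2 = NULL, ridge = 1e-4, gamma = 0.1,
                        sample_threshold = 0.01, prune_size = 50L,
                        num_mc_samples = 16L, p0 = NULL, adjust_z = TRUE) {
  if (!is.null(nsigma2) && nsigma2 <= 0) stop("`nsigma2` must be positive")
  if (ridge < 0) stop("`ridge` must be nonnegative")
  if (gamma <= 0 || gamma >= 1) stop("`gamma` must be in (0, 1)")
  if (sample_threshold <= 0 || sample_threshold >= 1) {
    stop("`sample_threshold` must be in (0, 1)")
  }
  prune_size <- as.integer(prune_size)
  if (prune_size < 1L) stop("`prune_size` must be positive")
  num_mc_samples <- as.integer(num_mc_samples)
  if (num_mc_samples < 1L) stop("`num_mc_samples` must be positive")
  if (!is.null(p0) && (p0 <= 0 || p0 >= 1)) stop("`p0` must be in (0, 1)")
  structure(list(nsigma2 = nsigma2, ridge = ridge, gamma = gamma,
                 sample_threshold = sample_threshold, prune_size = prune_size,
                 num_mc_samples = num_mc_samples, p0 = p0,
                 adjust_z = isTRUE(adjust_z)),
            class = "model_hyper")
}

# z-scores on the scale the likelihood model is evaluated on.
model_z <- function(summary, hyper) {
  if (!isTRUE(hyper$adjust_z)) return(summary$z)
  n <- summary$n_samples
  sqrt(n) * summary$z / sqrt(pmax(n - 2, 1) + summary$z^2)
}

resolve_p0 <- function(hyper, m) if (is.null(hyper$p0)) 1 / m else hyper$p0

# Moment estimate of the prior effect variance when not fixed by the user.
resolve_nsigma2 <- function(hyper, summary) {
  if (!is.null(hyper$nsigma2)) return(hyper$nsigma2)
  max(max(model_z(summary, hyper)^2) - 1, 1)
}

# Regularized LD matrix used everywhere the likelihood touches LD.
regularized_ld <- function(summary, hyper) {
  A <- summary$ld
  if (hyper$ridge > 0) diag(A) <- diag(A) + hyper$ridge
  A
}

#' Marginal covariance of z-scores under a causal configuration
#'
#' The z-scores of a locus are modeled as multivariate normal with mean zero
#' and covariance `A + A (nsigma2 * diag(c)) A`, where `A` is the
#' (ridge-regularized) LD matrix and `c` is a relaxed or binary causal
#' vector. Relaxed entries in (0, 1) scale the prior effect variance of a
#' variant, which is how infinitesimal effects of non-causal variants are
#' accommodated.
#'
#' @param summary A [summary_input()] object.
#' @param c_vec Numeric vector in \[0, 1\], length m.
#' @param hyper A [model_hyper()] object.
#' @return Symmetric m x m covariance matrix.
#' @export
marginal_covariance <- function(summary, c_vec, hyper = model_hyper()) {
  stopifnot(inherits(summary, "summary_input"))
  c_vec <- as.numeric(c_vec)
  if (length(c_vec) != summary$m) {
    stop(sprintf("dimension mismatch: c has length %d, locus has %d variants",
                 length(c_vec), summary$m))
  }
  if (any(c_vec < 0) || any(c_vec > 1)) stop("`c_vec` must lie in [0, 1]")
  A <- regularized_ld(summary, hyper)
  ns2 <- resolve_nsigma2(hyper, summary)
  S <- A + A %*% (ns2 * c_vec * A)   # diag(c) A == c * A rowwise
  (S + t(S)) / 2
}

# Precomputed per-locus quantities shared by every likelihood evaluation:
# Cholesky of A, log det A, and the base quadratic form z' A^{-1} z.
likelihood_cache <- function(summary, hyper) {
  A <- regularized_ld(summary, hyper)
  R <- tryCatch(chol(A), error = function(e) {
    ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "LD matrix not positive definite (smallest eigenvalue %.3e); raise `ridge`",
      ev))
  })
  zm <- model_z(summary, hyper)
  u <- backsolve(R, zm, transpose = TRUE)
  list(A = A, logdet_A = 2 * sum(log(diag(R))), quad_A = sum(u^2),
       z = zm, m = summary$m,
       nsigma2 = resolve_nsigma2(hyper, summary))
}

# Rank-k log-likelihood via the matrix inversion/determinant lemmas.
# Sigma = A + U D U' with U = A[, S] and D = nsigma2 * diag(c_S), so
# U' A^{-1} U = A[S, S] and U' A^{-1} z = z[S]; only k x k algebra remains.
# Returns the log density, optionally with the gradient wrt c_S.
loglik_rank_k <- function(cache, support, c_sup, grad = FALSE) {
  m <- cache$m
  base <- -0.5 * (m * log(2 * pi) + cache$logdet_A + cache$quad_A)
  k <- length(support)
  if (k == 0L) {
    return(if (grad) list(value = base, grad = numeric(0)) else base)
  }
  d <- cache$nsigma2 * c_sup
  Ass <- cache$A[support, support, drop = FALSE]
  ds <- sqrt(d)
  Ms <- diag(k) + (ds %o% ds) * Ass
  Rm <- tryCatch(chol(Ms), error = function(e) {
    ev <- min(eigen(Ms, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "marginal covariance not positive definite (smallest eigenvalue %.3e)",
      ev))
  })
  zs <- cache$z[support]
  w <- ds * zs
  u <- backsolve(Rm, w, transpose = TRUE)
  val <- base - sum(log(diag(Rm))) + 0.5 * sum(u^2)
  if (!grad) return(val)
  # d loglik / d c_i = 0.5 nsigma2 [ (s_i' Sigma^{-1} z)^2 - s_i' Sigma^{-1} s_i ]
  # with s_i = A[, i]; restricted to the support everything is k x k:
  #   A Sigma^{-1} z |_S      = z_S - A_SS K^{-1} z_S
  #   (A Sigma^{-1} A)_{ii}|_S = A_SS - A_SS K^{-1} A_SS (diagonal)
  # where K^{-1} = D^{1/2} Ms^{-1} D^{1/2}.
  Kinv_zs <- ds * backsolve(Rm, backsolve(Rm, w, transpose = TRUE))
  sz <- zs - drop(Ass %*% Kinv_zs)
  KinvA <- ds * backsolve(Rm, backsolve(Rm, ds * Ass, transpose = TRUE))
  sii <- diag(Ass) - rowSums(Ass * t(KinvA))
  list(value = val, grad = 0.5 * cache$nsigma2 * (sz^2 - sii))
}

# Dense log-likelihood oracle path (full m x m Cholesky).
loglik_dense <- function(summary, c_vec, hyper) {
  S <- marginal_covariance(summary, c_vec, hyper)
  R <- tryCatch(chol(S), error = function(e) {
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "marginal covariance not positive definite (smallest eigenvalue %.3e); raise `ridge`",
      ev))
  })
  u <- backsolve(R, model_z(summary, hyper), transpose = TRUE)
  -0.5 * (summary$m * log(2 * pi) + 2 * sum(log(diag(R))) + sum(u^2))
}

#' Marginal log-likelihood of the z-scores given a causal vector
#'
#' Log of the multivariate normal density of `z` under
#' [marginal_covariance()]. When the causal vector is sparse (support of at
#' most `prune_size` variants) the evaluation uses a rank-k update of the
#' base LD Cholesky instead of a dense m x m factorization; the two paths
#' agree to near machine precision.
#'
#' @param summary A [summary_input()] object.
#' @param c_vec Numeric causal vector in \[0, 1\], length m.
#' @param hyper A [model_hyper()] object.
#' @param support Optional integer indices of the nonzero entries of `c_vec`;
#'   entries off the support must be zero. `NULL` (default) autodetects.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(summary, c_vec, hyper = model_hyper(),
                           support = NULL) {
  stopifnot(inherits(summary, "summary_input"))
  c_vec <- as.numeric(c_vec)
  if (length(c_vec) != summary$m) stop("`c_vec` must have length m")
  if (is.null(support)) {
    support <- which(c_vec != 0)
  } else {
    support <- as.integer(support)
    off <- setdiff(which(c_vec != 0), support)
    if (length(off)) stop("`c_vec` must be zero off the given support")
  }
  if (length(support) <= hyper$prune_size) {
    cache <- likelihood_cache(summary, hyper)
    loglik_rank_k(cache, support, c_vec[support])
  } else {
    loglik_dense(summary, c_vec, hyper)
  }
}

#' Log prior probability of a binary causal configuration
#'
#' Independent Bernoulli(`p0`) prior over the m inclusion indicators, the
#' zero-temperature limit of the element-wise binary concrete prior.
#'
#' @param bits Binary vector (0/1) of length m.
#' @param p0 Scalar prior inclusion probability in (0, 1).
#' @return Scalar log prior probability.
#' @export
config_log_prior <- function(bits, p0) {
  bits <- as.numeric(bits)
  if (any(!bits %in% c(0, 1))) stop("`bits` must be binary")
  if (length(p0) != 1L || p0 <= 0 || p0 >= 1) stop("`p0` must be in (0, 1)")
  k <- sum(bits)
  k * log(p0) + (length(bits) - k) * log1p(-p0)
}
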