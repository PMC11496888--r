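#' Simulation scenario for a synthetic GWAS locus
#'
#' Defines the generative conditions for one simulated locus: `m` variants
#' across `n` individuals, `d` causal variants, total genetic variance
#' fraction `omega2`, and fraction `p_causal` of that genetic variance
#' attributed to the causal variants (the remainder is polygenic background
#' from the non-causal variants). Genotypes come from a block-structured
#' thresholded-Gaussian haplotype model rather than resampled reference
#' haplotypes, so no external data is needed.
#'
#' @param m Variant count (default 1000).
#' @param n Individual count (default 5000).
#' @param d Causal variant count, `d < m` (default 1).
#' @param omega2 Total genetic variance fraction in (0, 1) (default 0.5).
#' @param p_causal Causal fraction of genetic variance in (0, 1\] (default 0.9).
#' @param ld_block_size Variants per LD block (default 20).
#' @param ld_decay Within-block latent correlation decay in \[0, 1)
#'   (default 0.9; adjacent-variant latent correlation).
#' @param maf_min Minor allele frequency floor (default 0.02).
#' @param seed Integer RNG seed.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(m = 1000L, n = 5000L, d = 1L, omega2 = 0.5,
                         p_causal = 0.9, ld_block_size = 20L, ld_decay = 0.9,
                         maf_min = 0.02, seed = 1L) {
  m <- as.integer(m); n <- as.integer(n); d <- as.integer(d)
  if (d < 1L || d >= m) stop("`d` must satisfy 1 <= d < m")
  if (omega2 <= 0 || omega2 >= 1) stop("`omega2` must be in (0, 1)")
  if (p_causal <= 0 || p_causal > 1) stop("`p_causal` must be in (0, 1]")
  if (ld_decay < 0 || ld_decay >= 1) stop("`ld_decay` must be in [0, 1)")
  if (maf_min <= 0 || maf_min >= 0.5) stop("`maf_min` must be in (0, 0.5)")
  structure(list(m = m, n = n, d = d, omega2 = omega2, p_causal = p_causal,
                 ld_block_size = as.integer(ld_block_size),
                 ld_decay = ld_decay, maf_min = maf_min,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# One haplotype panel: latent AR(1) Gaussians per LD block, thresholded at
# per-variant quantiles so allele 1 has the target frequency.
draw_haplotypes <- function(n_hap, m, block_size, decay, freqs) {
  lat <- matrix(0, n_hap, m)
  start <- 1L
  while (start <= m) {
    end <- min(start + block_size - 1L, m)
    lat[, start] <- stats::rnorm(n_hap)
    if (end > start) {
      s <- sqrt(1 - decay^2)
      for (j in (start + 1L):end) {
        lat[, j] <- decay * lat[, j - 1L] + s * stats::rnorm(n_hap)
      }
    }
    start <- end + 1L
  }
  sweep(lat, 2, stats::qnorm(freqs), "<") * 1L
}

#' Simulate LD-correlated genotypes
#'
#' Each individual is the sum of two independent haplotypes. Haplotype
#' alleles arise by thresholding a block-structured latent Gaussian (within a
#' block, latent correlation decays as `ld_decay^|i-j|`; blocks are
#' independent) at the quantile matching a target allele frequency drawn
#' uniformly from `(maf_min, 0.5)`. Variants whose empirical minor allele
#' frequency falls below `maf_min` are re-thresholded with a fresh target
#' frequency (bounded retries), preserving the latent LD structure.
#' Causal variants are drawn uniformly without replacement.
#'
#' @param scenario A [sim_scenario()] object. Uses the current RNG state;
#'   seed via [set.seed()] or let [simulate_locus()] manage seeding.
#' @return An object of class `"genotype_panel"`: `genotypes_raw` (n x m
#'   allele counts 0/1/2), `genotypes_std` (columns centered and scaled to
#'   population variance 1), `causal_indices`, `mafs`.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  m <- scenario$m; n <- scenario$n
  freqs <- stats::runif(m, scenario$maf_min, 0.5)
  h1 <- draw_haplotypes(n, m, scenario$ld_block_size, scenario$ld_decay, freqs)
  h2 <- draw_haplotypes(n, m, scenario$ld_block_size, scenario$ld_decay, freqs)
  geno <- h1 + h2
  maf <- function(g) pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  mafs <- maf(geno)
  tries <- 0L
  while (any(bad <- mafs < scenario$maf_min)) {
    tries <- tries + 1L
    if (tries > 20L) {
      stop(sprintf("variant %d: could not attain MAF >= %.3f after 20 redraws",
                   which(bad)[1], scenario$maf_min))
    }
    idx <- which(bad)
    # failing columns get a fresh target frequency away from the floor and
    # independent latents; only the redrawn columns lose their block LD
    newf <- stats::runif(length(idx), min(2 * scenario$maf_min, 0.45), 0.5)
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      q <- stats::qnorm(newf[jj])
      geno[, j] <- (stats::rnorm(n) < q) + (stats::rnorm(n) < q)
    }
    mafs <- maf(geno)
  }
  mu <- colMeans(geno)
  sdv <- sqrt(colMeans(geno^2) - mu^2)   # population (1/n) variance
  std <- sweep(sweep(geno, 2, mu, "-"), 2, sdv, "/")
  structure(list(genotypes_raw = geno, genotypes_std = std,
                 causal_indices = sort(sample.int(m, scenario$d)),
                 mafs = mafs),
            class = "genotype_panel")
}

#' Simulate a mixed-model polygenic phenotype
#'
#' The phenotype combines fixed effects of the `d` causal variants with a
#' polygenic random effect of the remaining variants and Gaussian noise:
#' causal effects `beta ~ N(0, I_d)` give `g_C = X_C beta`; the non-causal
#' component is `g_NC = X_NC u` with `u ~ N(0, I/(m-d))` (equivalently
#' `g_NC ~ N(0, X_NC X_NC' / (m-d))`). The components are rescaled by their
#' empirical variances so the causal part explains `p_causal * omega2`, the
#' background `(1 - p_causal) * omega2`, and the noise `1 - omega2` of the
#' phenotypic variance.
#'
#' @param panel A [simulate_genotypes()] result.
#' @param scenario The matching [sim_scenario()].
#' @return List of class `"phenotype"` with `values` (length n), `beta`
#'   (causal effect draws), and the variance components used.
#' @export
simulate_phenotype <- function(panel, scenario) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(scenario, "sim_scenario"))
  X <- panel$genotypes_std
  n <- nrow(X); m <- ncol(X)
  cidx <- panel$causal_indices
  d <- length(cidx)
  if (d < 1L) stop("at least one causal variant is required")
  pvar <- function(x) mean((x - mean(x))^2)
  beta <- stats::rnorm(d)
  g_c <- drop(X[, cidx, drop = FALSE] %*% beta)
  if (pvar(g_c) == 0) {
    beta <- stats::rnorm(d)
    g_c <- drop(X[, cidx, drop = FALSE] %*% beta)
    if (pvar(g_c) == 0) stop("degenerate causal component after redraw")
  }
  u <- stats::rnorm(m - d) / sqrt(m - d)
  g_nc <- drop(X[, -cidx, drop = FALSE] %*% u)
  w2 <- scenario$omega2; p <- scenario$p_causal
  y <- sqrt(p * w2 / pvar(g_c)) * g_c +
    sqrt((1 - p) * w2 / pvar(g_nc)) * g_nc +
    stats::rnorm(n, sd = sqrt(1 - w2))
  structure(list(values = y, beta = beta,
                 var_causal = p * w2, var_background = (1 - p) * w2,
                 var_noise = 1 - w2),
            class = "phenotype")
}

#' GWAS summary statistics from a simulated locus
#'
#' Per-variant simple linear regression (with intercept) of the phenotype on
#' the raw allele counts; z-scores are the OLS slope over its standard
#' error. The LD matrix is `X'X / n` on the standardized genotypes, giving
#' an exact unit diagonal.
#'
#' @param panel A [simulate_genotypes()] result.
#' @param pheno A [simulate_phenotype()] result (or numeric vector).
#' @return A [summary_input()] object.
#' @export
gwas_summary <- function(panel, pheno) {
  stopifnot(inherits(panel, "genotype_panel"))
  y <- if (inherits(pheno, "phenotype")) pheno$values else as.numeric(pheno)
  G <- panel$genotypes_raw
  n <- nrow(G)
  if (n <= 2L) stop("OLS needs n > 2")
  if (length(y) != n) stop("phenotype length must equal the individual count")
  gc_ <- sweep(G, 2, colMeans(G), "-")
  sxx <- colSums(gc_^2)
  if (any(sxx == 0)) {
    stop(sprintf("monomorphic genotype column %d", which(sxx == 0)[1]))
  }
  yc <- y - mean(y)
  bhat <- colSums(gc_ * yc) / sxx
  rss <- sum(yc^2) - bhat^2 * sxx
  se <- sqrt(rss / (n - 2) / sxx)
  z <- bhat / se
  ld <- crossprod(panel$genotypes_std) / n
  ld <- (ld + t(ld)) / 2
  diag(ld) <- 1
  summary_input(z = z, ld = ld, n_samples = n)
}

#' Simulate one full locus: genotypes, phenotype, summary statistics
#'
#' Seeds the RNG from `scenario$seed`, then runs [simulate_genotypes()],
#' [simulate_phenotype()], and [gwas_summary()]. Bit-reproducible for a
#' fixed scenario.
#'
#' @param scenario A [sim_scenario()] object.
#' @return List of class `"sim_locus"`: `summary` ([summary_input()]),
#'   `truth` (binary causal indicator of length m), `causal_indices`,
#'   `beta`, `panel`, `phenotype`, `scenario`.
#' @export
simulate_locus <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  panel <- simulate_genotypes(scenario)
  pheno <- simulate_phenotype(panel, scenario)
  summ <- gwas_summary(panel, pheno)
  truth <- integer(scenario$m)
  truth[panel$causal_indices] <- 1L
  structure(list(summary = summ, truth = truth,
                 causal_indices = panel$causal_indices, beta = pheno$beta,
                 panel = panel, phenotype = pheno, scenario = scenario),
            class = "sim_locus")
}

#' Cartesian grid of simulation scenarios
#'
#' Builds one scenario per combination of causal count, genetic variance,
#' causal fraction, and replicate, with deterministic pairwise-distinct
#' seeds derived from `base_seed` by counter.
#'
#' @param d_values Integer vector of causal counts.
#' @param omega2_values Numeric vector of total genetic variance fractions.
#' @param p_values Numeric vector of causal variance fractions.
#' @param replicates Replicates per combination.
#' @param base_seed Integer base seed.
#' @param ... Further arguments (m, n, ld parameters) passed to
#'   [sim_scenario()] for every grid point.
#' @return List of [sim_scenario()] objects, length
#'   `length(d_values) * length(omega2_values) * length(p_values) * replicates`.
#' @export
scenario_grid <- function(d_values = c(1L, 4L, 8L, 12L),
                          omega2_values = c(0.1, 0.2, 0.4, 0.5, 0.7, 0.8),
                          p_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          replicates = 20L, base_seed = 1L, ...) {
  if (!length(d_values) || !length(omega2_values) || !length(p_values)) {
    stop("value lists must be nonempty")
  }
  grid <- expand.grid(rep = seq_len(replicates), p_causal = p_values,
                      omega2 = omega2_values, d = d_values,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    sim_scenario(d = grid$d[i], omega2 = grid$omega2[i],
                 p_causal = grid$p_causal[i],
                 seed = as.integer(base_seed) + i - 1L, ...)
  })
}
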