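test_that("scenario validation and the full-grid count", {
  expect_error(sim_scenario(m = 10, d = 10), "d")
  expect_error(sim_scenario(omega2 = 1.2), "omega2")
  grid <- scenario_grid(m = 100, n = 500)
  expect_length(grid, 4 * 6 * 5 * 20)
  seeds <- vapply(grid, `[[`, integer(1), "seed")
  expect_false(any(duplicated(seeds)))
  expect_length(scenario_grid(1, 0.5, 0.9, replicates = 1, m = 50, n = 100), 1L)
})

test_that("genotype panels are reproducible, standardized, and MAF-filtered", {
  sc <- sim_scenario(m = 60, n = 800, d = 2, seed = 9)
  set.seed(sc$seed); p1 <- simulate_genotypes(sc)
  set.seed(sc$seed); p2 <- simulate_genotypes(sc)
  expect_identical(p1, p2)
  expect_true(all(p1$genotypes_raw %in% 0:2))
  expect_true(all(abs(colMeans(p1$genotypes_std)) < 1e-8))
  expect_true(all(abs(colMeans(p1$genotypes_std^2) - 1) < 1e-6))
  expect_true(all(p1$mafs >= sc$maf_min))
  expect_length(p1$causal_indices, 2L)
})

test_that("ld_decay controls the empirical correlation structure", {
  sc0 <- sim_scenario(m = 40, n = 2000, d = 1, ld_decay = 0, seed = 31)
  set.seed(31)
  panel <- simulate_genotypes(sc0)
  ld <- crossprod(panel$genotypes_std) / sc0$n
  off <- abs(ld[upper.tri(ld)])
  expect_gt(mean(off < 4 / sqrt(sc0$n)), 0.99)

  # strong decay: adjacent empirical correlation matches a direct Monte
  # Carlo of the thresholded-Gaussian mapping within 0.1
  sc9 <- sim_scenario(m = 40, n = 5000, d = 1, ld_decay = 0.9, seed = 32)
  set.seed(32)
  panel9 <- simulate_genotypes(sc9)
  ld9 <- crossprod(panel9$genotypes_std) / sc9$n
  within_block <- setdiff(seq_len(39), seq(20, 39, by = 20))
  adj <- vapply(within_block, function(j) ld9[j, j + 1], numeric(1))
  set.seed(1)
  nmc <- 2e5
  x1 <- rnorm(nmc); x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(nmc)
  oracle <- mean(vapply(seq_len(30), function(i) {
    f <- runif(2, 0.02, 0.5)
    cor(x1 < qnorm(f[1]), x2 < qnorm(f[2]))
  }, numeric(1)))
  expect_lt(abs(mean(adj) - oracle), 0.1)
})

test_that("phenotype variance decomposition follows the target fractions", {
  sc <- sim_scenario(m = 200, n = 5000, d = 4, omega2 = 0.5, p_causal = 0.7,
                     seed = 41)
  set.seed(sc$seed)
  panel <- simulate_genotypes(sc)
  ph <- simulate_phenotype(panel, sc)
  expect_lt(abs(mean((ph$values - mean(ph$values))^2) - 1), 0.05)

  # squared correlation with the full genetic component approximates omega2
  r2 <- vapply(1:20, function(i) {
    sc_i <- sim_scenario(m = 100, n = 2000, d = 2, omega2 = 0.4,
                         p_causal = 0.5, seed = 600 + i)
    set.seed(sc_i$seed)
    pan <- simulate_genotypes(sc_i)
    ph_i <- simulate_phenotype(pan, sc_i)
    X <- pan$genotypes_std
    fitted <- drop(X %*% qr.solve(crossprod(X) + diag(1e-6, ncol(X)),
                                  crossprod(X, ph_i$values)))
    cor(fitted, ph_i$values)^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.4), 0.1)
})

test_that("p_causal = 1 removes the polygenic background", {
  sc <- sim_scenario(m = 50, n = 500, d = 2, omega2 = 0.5, p_causal = 1,
                     seed = 55)
  set.seed(sc$seed)
  panel <- simulate_genotypes(sc)
  ph <- simulate_phenotype(panel, sc)
  expect_equal(ph$var_background, 0)
})

test_that("null GWAS z-scores are standard normal; LD diagonal is exactly 1", {
  sc <- sim_scenario(m = 1000, n = 300, d = 1, seed = 61)
  set.seed(sc$seed)
  panel <- simulate_genotypes(sc)
  y <- rnorm(sc$n)  # phenotype independent of every genotype
  s <- gwas_summary(panel, y)
  expect_equal(diag(s$ld), rep(1, 1000))
  ks <- suppressWarnings(ks.test(s$z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_error(gwas_summary(panel, y[1:10]), "length")
})

test_that("the causal variant usually has the top z-score in strong scenarios", {
  hits <- vapply(1:20, function(i) {
    loc <- simulate_locus(sim_scenario(m = 100, n = 1000, d = 1, omega2 = 0.5,
                                       p_causal = 0.9, seed = 700 + i))
    which.max(abs(loc$summary$z)) == loc$causal_indices
  }, logical(1))
  expect_gte(sum(hits), 15L)
})

test_that("summary pipeline is deterministic, PSD, and shows inflation", {
  sc <- sim_scenario(m = 50, n = 500, d = 1, omega2 = 0.5, p_causal = 0.5,
                     seed = 71)
  l1 <- simulate_locus(sc)
  l2 <- simulate_locus(sc)
  expect_identical(l1$summary$z, l2$summary$z)
  expect_identical(l1$summary$ld, l2$summary$ld)
  ev <- eigen(l1$summary$ld, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # polygenicity inflates the mean chi-square at non-causal variants
  chisq <- vapply(1:20, function(i) {
    loc <- simulate_locus(sim_scenario(m = 50, n = 500, d = 1, omega2 = 0.5,
                                       p_causal = 0.5, seed = 800 + i))
    mean(loc$summary$z[-loc$causal_indices]^2)
  }, numeric(1))
  expect_gt(mean(chisq), 1)
})
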