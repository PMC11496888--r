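test_that("posterior over an explicit configuration set matches brute force", {
  set.seed(5)
  m <- 3
  ld <- random_corr(m)
  z <- c(3, 0.5, -1)
  s <- summary_input(z = z, ld = ld, n_samples = 400)
  hy <- model_hyper(nsigma2 = 20, adjust_z = FALSE)
  configs <- all_subsets(m)
  harvest <- harvested_configs(configs, m)
  red <- normalize_posterior(harvest, s, hy)
  expect_equal(sum(red$posterior), 1, tolerance = 1e-10)
  want <- ref_config_posterior(red$supports, z, ld, hy, n = 400)
  expect_equal(red$posterior, want, tolerance = 1e-10)
  # PIPs from the reduced set equal the exact Bayesian PIPs
  pips <- compute_pips(red)
  want_pips <- vapply(seq_len(m), function(i) {
    sum(want[vapply(red$supports, function(sup) i %in% sup, logical(1))])
  }, numeric(1))
  expect_equal(pips, want_pips, tolerance = 1e-10)
})

test_that("posterior handles singletons and symmetric configurations", {
  s <- summary_input(z = c(2, 2), ld = diag(2), n_samples = 100)
  hy <- model_hyper(nsigma2 = 10, p0 = 0.5)
  one <- normalize_posterior(harvested_configs(list(1L), 2), s, hy)
  expect_equal(length(one$posterior), 2L)  # null is always added
  solo <- normalize_posterior(
    structure(list(supports = list(1L), first_seen = 0L, m = 2L),
              class = "harvested_configs"), s, hy)
  expect_equal(solo$posterior, 1)
  # identical z and no LD: the two singleton configs split mass equally
  both <- normalize_posterior(harvested_configs(list(1L, 2L), 2), s, hy)
  i1 <- which(vapply(both$supports, identical, logical(1), 1L))
  i2 <- which(vapply(both$supports, identical, logical(1), 2L))
  expect_equal(both$posterior[i1], both$posterior[i2])
})

test_that("PIPs sum configuration masses per variant", {
  red <- structure(list(supports = list(1L, c(1L, 2L)),
                        log_weight = c(0, 0), posterior = c(0.5, 0.5),
                        m = 3L),
                   class = "reduced_config_set")
  expect_equal(compute_pips(red), c(1.0, 0.5, 0.0))
  red1 <- structure(list(supports = list(1L), log_weight = 0, posterior = 1,
                         m = 3L),
                    class = "reduced_config_set")
  expect_equal(compute_pips(red1), c(1, 0, 0))
  # expected causal count identity
  expect_equal(sum(compute_pips(red)),
               sum(red$posterior * lengths(red$supports)))
})

test_that("credible sets follow the greedy conditional construction", {
  # all mass on one configuration
  red <- structure(list(supports = list(2L), log_weight = 0, posterior = 1,
                        m = 3L),
                   class = "reduced_config_set")
  cs <- credible_sets(red)
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$members, 2L)
  # 0.6/0.4 split between two singletons: one set holding both variants
  red2 <- structure(list(supports = list(1L, 2L), log_weight = c(0, 0),
                         posterior = c(0.6, 0.4), m = 3L),
                    class = "reduced_config_set")
  cs2 <- credible_sets(red2, rho = 0.95)
  expect_length(cs2, 1L)
  expect_equal(cs2[[1]]$key_variant, 1L)
  expect_equal(cs2[[1]]$members, c(1L, 2L))
  # no variant reaches the stop threshold -> no sets
  red3 <- structure(list(supports = list(integer(0), 1L),
                         log_weight = c(0, 0), posterior = c(0.7, 0.3),
                         m = 3L),
                    class = "reduced_config_set")
  expect_length(credible_sets(red3), 0L)
})

test_that("two well-separated strong signals yield two covering sets", {
  success <- 0L
  tried <- 0L
  seed <- 500L
  while (tried < 10L) {
    seed <- seed + 1L
    sc <- sim_scenario(m = 100, n = 1500, d = 2, omega2 = 0.6,
                       p_causal = 0.9, seed = seed)
    loc <- simulate_locus(sc)
    # the property's premise: well-separated AND individually strong signals
    if (abs(diff(loc$causal_indices)) < 25) next
    if (any(abs(loc$summary$z[loc$causal_indices]) < 5)) next
    tried <- tried + 1L
    res <- finemap_locus(loc$summary,
                         train = train_config(num_steps = 500, seed = seed))
    covered <- vapply(loc$causal_indices, function(v) {
      any(vapply(res$credible_sets,
                 function(s) v %in% s$members, logical(1)))
    }, logical(1))
    if (all(covered)) success <- success + 1L
  }
  expect_gte(success, 7L)
})

test_that("exhaustive m = 8 locus: reduced-set PIPs equal exact PIPs", {
  sc <- sim_scenario(m = 8, n = 500, d = 1, omega2 = 0.3, p_causal = 0.9,
                     ld_block_size = 4, seed = 77)
  loc <- simulate_locus(sc)
  hy <- model_hyper()
  harvest <- harvested_configs(all_subsets(8), 8)
  red <- normalize_posterior(harvest, loc$summary, hy)
  pips <- compute_pips(red)
  want <- ref_config_posterior(red$supports, loc$summary$z, loc$summary$ld,
                               hy, n = loc$summary$n_samples)
  want_pips <- vapply(1:8, function(i) {
    sum(want[vapply(red$supports, function(sup) i %in% sup, logical(1))])
  }, numeric(1))
  expect_equal(pips, want_pips, tolerance = 1e-10)
  expect_true(all(pips >= 0 & pips <= 1))
})
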