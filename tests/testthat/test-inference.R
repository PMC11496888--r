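test_that("network forward pass is deterministic with the stated identity", {
  set.seed(1)
  net <- inference_network(6, p0 = 1 / 6)
  z <- rnorm(6)
  expect_identical(net_forward(net, z), net_forward(net, z))
  expect_error(net_forward(net, rnorm(5)), "width mismatch")
  # zeroed final layer leaves the constant sigmoid of the bias
  net$W3[] <- 0
  net$b3[] <- 0.3
  expect_equal(net_forward(net, z), rep(plogis(0.3), 6))
  # fresh network starts at the sparse prior
  set.seed(2)
  net2 <- inference_network(6, p0 = 0.05)
  net2$W3[] <- 0
  expect_equal(net_forward(net2, rnorm(6)), rep(0.05, 6))
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(33)
  m <- 5
  s <- summary_input(z = rnorm(m, sd = 1.5), ld = random_corr(m),
                     n_samples = 400)
  hy <- model_hyper(nsigma2 = 30)
  probs <- runif(m, 0.15, 0.85)
  lam <- 0.7
  uniforms <- matrix(runif(3 * m, 0.1, 0.9), 3, m)
  cache <- finecrete:::likelihood_cache(s, hy)
  analytic <- finecrete:::mc_objective(cache, probs, lam, hy, uniforms,
                                       grad = TRUE)$grad_probs
  h <- 1e-6
  numeric_g <- vapply(seq_len(m), function(i) {
    up <- probs; up[i] <- up[i] + h
    dn <- probs; dn[i] <- dn[i] - h
    (finemap_loss(s, up, lam, hy, uniforms) -
       finemap_loss(s, dn, lam, hy, uniforms)) / (2 * h)
  }, numeric(1))
  expect_equal(analytic, numeric_g, tolerance = 1e-4)
})

test_that("loss equals an independent composition of sampler, MVN, and KL", {
  set.seed(8)
  m <- 3
  ld <- random_corr(m)
  z <- c(1.2, -0.4, 2.5)
  s <- summary_input(z = z, ld = ld, n_samples = 500)
  hy <- model_hyper(nsigma2 = 12, ridge = 1e-4, adjust_z = FALSE)
  probs <- c(0.3, 0.6, 0.8)
  lam <- 0.5
  U <- matrix(runif(2 * m, 0.05, 0.95), 2, m)
  # reference: explicit relaxed samples -> covariance -> MVN density -> KL
  A <- ld; diag(A) <- diag(A) + 1e-4
  ll <- vapply(1:2, function(l) {
    cl <- plogis((qlogis(U[l, ]) + qlogis(probs)) / lam)
    cl[cl <= hy$sample_threshold] <- 0
    S <- A + A %*% (12 * cl * A)
    ref_mvn_logpdf(z, (S + t(S)) / 2)
  }, numeric(1))
  p0 <- 1 / m
  want <- -mean(ll) + sum(probs * log(probs / p0) +
                            (1 - probs) * log((1 - probs) / (1 - p0)))
  expect_equal(finemap_loss(s, probs, lam, hy, U), want, tolerance = 1e-9)
})

test_that("loss with an empty support is the null likelihood plus zero KL", {
  m <- 4
  s <- toy_summary(m, seed = 12, n = 300)
  hy <- model_hyper(nsigma2 = 10, adjust_z = FALSE)
  p0 <- 1 / m
  U <- matrix(1e-8, 1, m)  # forces every sample far below the threshold
  A <- s$ld; diag(A) <- diag(A) + hy$ridge
  want <- -ref_mvn_logpdf(s$z, A)
  expect_equal(finemap_loss(s, rep(p0, m), 0.5, hy, U), want,
               tolerance = 1e-9)
})

test_that("Monte Carlo averaging: more samples shrink the loss variance", {
  set.seed(21)
  m <- 4
  s <- toy_summary(m, seed = 21, n = 300)
  hy <- model_hyper(nsigma2 = 10)
  probs <- rep(0.3, m)
  losses <- function(L, reps) {
    vapply(seq_len(reps), function(r) {
      finemap_loss(s, probs, 0.5, hy, matrix(runif(L * m), L, m))
    }, numeric(1))
  }
  l1 <- losses(1L, 200)
  l2 <- losses(2L, 200)
  # unbiasedness: means agree within Monte Carlo error (5 SE)
  se <- sqrt(var(l1) / 200 + var(l2) / 200)
  expect_lt(abs(mean(l1) - mean(l2)), 5 * se)
  # variance halves (allow wide slack for 200 replicates)
  expect_lt(var(l2), 0.75 * var(l1))
})

test_that("training is reproducible and harvests bounded unique configs", {
  loc <- simulate_locus(sim_scenario(m = 40, n = 600, d = 1, omega2 = 0.5,
                                     p_causal = 0.9, seed = 17))
  tr <- train_config(num_steps = 60, num_mc_samples = 4, seed = 5)
  f1 <- fit_finemap(loc$summary, train = tr)
  f2 <- fit_finemap(loc$summary, train = tr)
  expect_identical(f1$probs, f2$probs)
  expect_identical(f1$harvest$supports, f2$harvest$supports)
  expect_identical(f1$trace, f2$trace)
  # dedup bound: at most T * L + 1 configurations, null always present
  expect_lte(length(f1$harvest$supports), 60 * 4 + 1)
  expect_true(any(lengths(f1$harvest$supports) == 0))
  # a different seed gives a different sample path
  f3 <- fit_finemap(loc$summary, train = train_config(num_steps = 60,
                                                      num_mc_samples = 4,
                                                      seed = 6))
  expect_false(identical(f1$trace, f3$trace))
})

test_that("zero training steps leave the network untouched, null-only harvest", {
  s <- toy_summary(5, seed = 3, n = 200)
  set.seed(1)
  net <- inference_network(5, p0 = 0.2)
  fit <- fit_finemap(s, train = train_config(num_steps = 0, seed = 9),
                     net = net)
  expect_identical(fit$net, net)
  expect_identical(fit$harvest$supports, list(integer(0)))
})

test_that("training reduces the loss and finds the causal variant", {
  hits <- 0L
  for (i in 1:5) {
    loc <- simulate_locus(sim_scenario(m = 50, n = 800, d = 1, omega2 = 0.5,
                                       p_causal = 0.9, seed = 400 + i))
    fit <- fit_finemap(loc$summary,
                       train = train_config(num_steps = 300, seed = 400 + i))
    first <- fit$trace[1]
    tail_mean <- mean(fit$trace[251:300])
    expect_lt(tail_mean, first)
    if (which.max(fit$probs) == loc$causal_indices) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
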