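#' Inference network mapping z-scores to a probability map
#'
#' A small multilayer perceptron F(z; phi): input the m z-scores of a locus,
#' two tanh hidden layers, and an m-unit sigmoid output clamped to
#' \[1e-6, 1 - 1e-6\] so the probability map stays strictly inside (0, 1).
#' The final-layer bias starts at logit(`p0`) so training begins near the
#' sparse prior. Weights use fan-in scaled Gaussian initialization from the
#' current RNG state.
#'
#' @param m Integer number of variants (input and output width).
#' @param p0 Prior inclusion probability used to center the output bias.
#' @param hidden Integer width of the two hidden layers; default
#'   `max(64, round(m / 4))`.
#' @return An object of class `"inference_network"`.
#' @export
inference_network <- function(m, p0 = 1 / m, hidden = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be positive")
  if (is.null(hidden)) hidden <- max(64L, as.integer(round(m / 4)))
  h <- as.integer(hidden)
  rmat <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  }
  structure(list(
    W1 = rmat(h, m), b1 = numeric(h),
    W2 = rmat(h, h), b2 = numeric(h),
    W3 = rmat(m, h), b3 = rep(stats::qlogis(p0), m),
    m = m, hidden = h
  ), class = "inference_network")
}

PROB_CLAMP <- 1e-6

#' Forward pass of the inference network
#'
#' Deterministic given the weights; returns the probability map p = F(z; phi)
#' clamped to \[1e-6, 1 - 1e-6\].
#'
#' @param net An [inference_network()].
#' @param z Numeric z-score vector of length `net$m`.
#' @return Numeric probability vector of length `net$m` strictly in (0, 1).
#' @export
net_forward <- function(net, z) {
  net_forward_full(net, z)$probs
}

# Forward pass retaining intermediate activations for backpropagation.
net_forward_full <- function(net, z) {
  stopifnot(inherits(net, "inference_network"))
  z <- as.numeric(z)
  if (length(z) != net$m) {
    stop(sprintf("width mismatch: network expects %d inputs, got %d",
                 net$m, length(z)))
  }
  h1 <- tanh(drop(net$W1 %*% z) + net$b1)
  h2 <- tanh(drop(net$W2 %*% h1) + net$b2)
  o <- drop(net$W3 %*% h2) + net$b3
  p_raw <- stats::plogis(o)
  probs <- pmin(pmax(p_raw, PROB_CLAMP), 1 - PROB_CLAMP)
  list(z = z, h1 = h1, h2 = h2, p_raw = p_raw, probs = probs)
}

# Backpropagate dL/dprobs to gradients in the network weights. Clamped
# outputs pass the sigmoid derivative of the clamped value, which is ~0.
net_backward <- function(net, fwd, d_probs) {
  d_o <- d_probs * fwd$probs * (1 - fwd$probs)
  g_W3 <- d_o %o% fwd$h2
  g_b3 <- d_o
  d_h2 <- drop(crossprod(net$W3, d_o)) * (1 - fwd$h2^2)
  g_W2 <- d_h2 %o% fwd$h1
  g_b2 <- d_h2
  d_h1 <- drop(crossprod(net$W2, d_h2)) * (1 - fwd$h1^2)
  g_W1 <- d_h1 %o% fwd$z
  g_b1 <- d_h1
  list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2, W3 = g_W3, b3 = g_b3)
}

#' Training configuration
#'
#' @param num_steps Number of gradient steps T (default 1000).
#' @param num_mc_samples Monte Carlo samples L per step (default 16).
#' @param step_size Adam learning rate (default 1e-2).
#' @param anneal An [anneal_schedule()]; `NULL` (default) means a linear
#'   schedule from 0.5 to 0.01 over `num_steps`.
#' @param seed Integer RNG seed controlling initialization and sampling.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(num_steps = 1000L, num_mc_samples = 16L,
                         step_size = 1e-2, anneal = NULL, seed = 1L) {
  num_steps <- as.integer(num_steps)
  if (num_steps < 0L) stop("`num_steps` must be nonnegative")
  num_mc_samples <- as.integer(num_mc_samples)
  if (num_mc_samples < 1L) stop("`num_mc_samples` must be positive")
  if (step_size <= 0) stop("`step_size` must be positive")
  if (is.null(anneal)) {
    anneal <- anneal_schedule(0.5, 0.01, max(num_steps, 1L))
  }
  stopifnot(inherits(anneal, "anneal_schedule"))
  structure(list(num_steps = num_steps, num_mc_samples = num_mc_samples,
                 step_size = step_size, anneal = anneal,
                 seed = as.integer(seed)),
            class = "train_config")
}

# One Monte Carlo evaluation of the variational objective:
#   loss = -(1/L) sum_l log N(z; 0, Sigma(c_l)) + KL(Bern(probs) || Bern(p0))
# where c_l is the reparameterized binary concrete draw, support-thresholded
# and pruned before the likelihood. Returns the loss, the gradient wrt probs
# (through retained entries only), and the binarized configurations.
mc_objective <- function(cache, probs, lambda, hyper, uniforms,
                         grad = TRUE) {
  m <- length(probs)
  L <- nrow(uniforms)
  logit_p <- stats::qlogis(probs)
  cmat <- stats::plogis((stats::qlogis(uniforms) +
                           rep(logit_p, each = L)) / lambda)
  ll_sum <- 0
  grad_ll <- if (grad) numeric(m) else NULL
  configs <- vector("list", L)
  for (l in seq_len(L)) {
    cl <- cmat[l, ]
    configs[[l]] <- which(cl > hyper$gamma)
    sup <- which(cl > hyper$sample_threshold)
    if (length(sup) > hyper$prune_size) {
      sup <- sup[order(cl[sup], decreasing = TRUE)[seq_len(hyper$prune_size)]]
    }
    res <- loglik_rank_k(cache, sup, cl[sup], grad = grad)
    if (grad) {
      ll_sum <- ll_sum + res$value
      if (length(sup)) {
        cs <- cl[sup]
        dcdp <- cs * (1 - cs) / (lambda * probs[sup] * (1 - probs[sup]))
        grad_ll[sup] <- grad_ll[sup] + res$grad * dcdp
      }
    } else {
      ll_sum <- ll_sum + res
    }
  }
  p0 <- resolve_p0(hyper, m)
  value <- -ll_sum / L + kl_bernoulli(probs, p0)
  out <- list(value = value, configs = configs)
  if (grad) {
    out$grad_probs <- -grad_ll / L + (logit_p - stats::qlogis(p0))
  }
  out
}

#' Variational loss at a fixed probability map
#'
#' The Monte Carlo estimate of the objective minimized during training: the
#' negative average log-likelihood of the z-scores over L reparameterized
#' binary concrete draws (each support-thresholded at
#' `hyper$sample_threshold` and pruned to `hyper$prune_size` entries), plus
#' the Bernoulli KL regularizer toward the sparse prior.
#'
#' @param summary A [summary_input()] object.
#' @param probs Probability map strictly inside (0, 1), length m.
#' @param lambda Positive relaxation temperature.
#' @param hyper A [model_hyper()] object.
#' @param uniforms L x m matrix of uniforms strictly inside (0, 1).
#' @return Scalar loss value.
#' @export
finemap_loss <- function(summary, probs, lambda, hyper = model_hyper(),
                         uniforms) {
  stopifnot(inherits(summary, "summary_input"))
  uniforms <- as.matrix(uniforms)
  if (ncol(uniforms) != summary$m) stop("`uniforms` must have m columns")
  if (any(uniforms <= 0) || any(uniforms >= 1)) {
    stop("`uniforms` must lie strictly inside (0, 1)")
  }
  cache <- likelihood_cache(summary, hyper)
  mc_objective(cache, probs, lambda, hyper, uniforms, grad = FALSE)$value
}

#' Construct a set of causal configurations by hand
#'
#' Mostly useful for evaluating the posterior over an explicit configuration
#' list (e.g. every configuration of a small locus) instead of the set
#' harvested during training. Duplicates are removed; the all-zero (null)
#' configuration is added when absent.
#'
#' @param supports List of integer vectors, each the set of causal variant
#'   indices of one configuration (the empty vector is the null
#'   configuration).
#' @param m Locus variant count.
#' @return An object of class `"harvested_configs"`.
#' @export
harvested_configs <- function(supports, m) {
  m <- as.integer(m)
  supports <- lapply(supports, function(s) sort(unique(as.integer(s))))
  if (any(vapply(supports, function(s) length(s) && (min(s) < 1L || max(s) > m),
                 logical(1)))) {
    stop("configuration indices must lie in 1..m")
  }
  keys <- vapply(supports, paste, character(1), collapse = ",")
  supports <- supports[!duplicated(keys)]
  if (!any(lengths(supports) == 0L)) supports <- c(list(integer(0)), supports)
  structure(list(supports = supports,
                 first_seen = rep(0L, length(supports)), m = m),
            class = "harvested_configs")
}

#' @export
print.harvested_configs <- function(x, ...) {
  cat(sprintf("harvested_configs: %d unique configurations over %d variants\n",
              length(x$supports), x$m))
  invisible(x)
}

#' Fit the variational fine-mapping model to one locus
#'
#' Runs T Adam steps on the inference network weights. At each step the
#' network produces the probability map, L binary concrete samples are
#' drawn at the current annealed temperature, each sample is binarized at
#' `hyper$gamma` and its unique binarization added to the reduced
#' configuration set (the all-zero configuration is always included), the
#' sample support is thresholded and pruned before the likelihood, and the
#' loss gradient is backpropagated. Fully reproducible given
#' `train$seed`.
#'
#' @param summary A [summary_input()] object.
#' @param hyper A [model_hyper()] object.
#' @param train A [train_config()] object.
#' @param net Optional pre-built [inference_network()]; default builds one
#'   from the locus width under the seeded RNG.
#' @return A list of class `"finemap_fit"` with elements `net` (trained
#'   network), `harvest` (`harvested_configs`: unique binary configurations
#'   as sorted support index vectors plus first-seen step), `probs` (final
#'   probability map), and `trace` (per-step loss).
#' @export
fit_finemap <- function(summary, hyper = model_hyper(),
                        train = train_config(), net = NULL) {
  stopifnot(inherits(summary, "summary_input"),
            inherits(hyper, "model_hyper"),
            inherits(train, "train_config"))
  m <- summary$m
  set.seed(train$seed)
  if (is.null(net)) net <- inference_network(m, p0 = resolve_p0(hyper, m))
  if (net$m != m) stop("network width does not match the locus")
  cache <- likelihood_cache(summary, hyper)
  L <- train$num_mc_samples

  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign("null", TRUE, envir = seen)
  supports <- list(integer(0))
  first_seen <- 0L

  par_names <- c("W1", "b1", "W2", "b2", "W3", "b3")
  mom1 <- lapply(net[par_names], function(w) w * 0)
  mom2 <- lapply(net[par_names], function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- numeric(train$num_steps)
  fwd <- NULL

  for (t in seq_len(train$num_steps)) {
    lam <- temperature_at(train$anneal, t)
    fwd <- net_forward_full(net, summary$z)
    uniforms <- matrix(stats::runif(L * m), L, m)
    obj <- mc_objective(cache, fwd$probs, lam, hyper, uniforms, grad = TRUE)
    if (!is.finite(obj$value)) {
      stop(sprintf("non-finite loss at step %d (lambda = %.4g)", t, lam))
    }
    trace[t] <- obj$value
    for (cfg in obj$configs) {
      key <- if (length(cfg)) paste(cfg, collapse = ",") else "null"
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        supports[[length(supports) + 1L]] <- cfg
        first_seen <- c(first_seen, t)
      }
    }
    grads <- net_backward(net, fwd, obj$grad_probs)
    for (nm in par_names) {
      mom1[[nm]] <- beta1 * mom1[[nm]] + (1 - beta1) * grads[[nm]]
      mom2[[nm]] <- beta2 * mom2[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mom1[[nm]] / (1 - beta1^t)
      vhat <- mom2[[nm]] / (1 - beta2^t)
      net[[nm]] <- net[[nm]] - train$step_size * mhat / (sqrt(vhat) + eps)
    }
  }

  harvest <- structure(list(supports = supports, first_seen = first_seen,
                            m = m),
                       class = "harvested_configs")
  structure(list(net = net, harvest = harvest,
                 probs = net_forward(net, summary$z), trace = trace),
            class = "finemap_fit")
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat(sprintf(
    "finemap_fit: %d configurations harvested; final loss %.3f; max prob %.3f\n",
    length(x$harvest$supports),
    if (length(x$trace)) x$trace[length(x$trace)] else NA_real_,
    max(x$probs)))
  invisible(x)
}
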