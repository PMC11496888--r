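#' Normalize the posterior over harvested causal configurations
#'
#' Each harvested binary configuration b is scored by
#' `log p(z | LD, b) + log p(b)` (multivariate-normal likelihood with c = b
#' and independent Bernoulli prior), and probabilities are normalized by
#' log-sum-exp over exactly the harvested set. Configurations whose
#' likelihood evaluation fails are dropped with a warning.
#'
#' @param harvest A `harvested_configs` object from [fit_finemap()].
#' @param summary The [summary_input()] the configurations were harvested on.
#' @param hyper A [model_hyper()] object.
#' @return An object of class `"reduced_config_set"` with `supports` (list of
#'   sorted variant index vectors), `log_weight` (unnormalized log posterior),
#'   `posterior` (normalized probabilities summing to 1), and `m`.
#' @export
normalize_posterior <- function(harvest, summary, hyper = model_hyper()) {
  stopifnot(inherits(harvest, "harvested_configs"),
            inherits(summary, "summary_input"))
  if (!length(harvest$supports)) stop("harvest must contain at least one configuration")
  if (harvest$m != summary$m) stop("harvest and summary disagree on m")
  m <- summary$m
  p0 <- resolve_p0(hyper, m)
  cache <- likelihood_cache(summary, hyper)
  lw <- vapply(harvest$supports, function(sup) {
    k <- length(sup)
    ll <- tryCatch({
      if (k <= hyper$prune_size) {
        loglik_rank_k(cache, sup, rep(1, k))
      } else {
        cv <- numeric(m); cv[sup] <- 1
        loglik_dense(summary, cv, hyper)
      }
    }, error = function(e) NA_real_)
    ll + k * log(p0) + (m - k) * log1p(-p0)
  }, numeric(1))
  keep <- is.finite(lw)
  if (!any(keep)) stop("likelihood evaluation failed for every configuration")
  if (!all(keep)) {
    warning(sprintf("dropped %d configuration(s) with failed likelihood",
                    sum(!keep)))
  }
  supports <- harvest$supports[keep]
  lw <- lw[keep]
  lse <- max(lw) + log(sum(exp(lw - max(lw))))
  structure(list(supports = supports, log_weight = lw,
                 posterior = exp(lw - lse), m = m),
            class = "reduced_config_set")
}

#' @export
print.reduced_config_set <- function(x, ...) {
  top <- order(x$posterior, decreasing = TRUE)[seq_len(min(3, length(x$posterior)))]
  cat(sprintf("reduced_config_set: %d configurations over %d variants\n",
              length(x$supports), x$m))
  for (i in top) {
    cat(sprintf("  {%s}: %.4f\n",
                paste(x$supports[[i]], collapse = ","), x$posterior[i]))
  }
  invisible(x)
}

#' Posterior inclusion probabilities
#'
#' The PIP of variant i is the summed posterior probability of every
#' configuration in the reduced set that includes variant i.
#'
#' @param reduced A [normalize_posterior()] result.
#' @return Numeric vector of length m with entries in \[0, 1\].
#' @export
compute_pips <- function(reduced) {
  stopifnot(inherits(reduced, "reduced_config_set"))
  pips <- numeric(reduced$m)
  for (j in seq_along(reduced$supports)) {
    sup <- reduced$supports[[j]]
    if (length(sup)) pips[sup] <- pips[sup] + reduced$posterior[j]
  }
  pmin(pips, 1)
}

# Conditional inclusion probabilities given that all variants in `given` are
# causal: restrict the reduced set to configurations containing `given`,
# renormalize, and sum inclusion per variant. NULL when no configuration
# supports the conditioning event.
conditional_inclusion <- function(reduced, given) {
  if (length(given)) {
    keep <- vapply(reduced$supports, function(s) all(given %in% s), logical(1))
  } else {
    keep <- rep(TRUE, length(reduced$supports))
  }
  mass <- sum(reduced$posterior[keep])
  if (!any(keep) || mass <= 0) return(NULL)
  q <- numeric(reduced$m)
  for (j in which(keep)) {
    sup <- reduced$supports[[j]]
    if (length(sup)) q[sup] <- q[sup] + reduced$posterior[j]
  }
  q / mass
}

#' Credible sets from the reduced configuration set
#'
#' Two-step construction. Step 1 selects "key" variants greedily: at each
#' round the variant with the largest conditional probability of being causal
#' given the previously selected keys is added, stopping when that maximal
#' conditional probability drops below `stop_threshold` (default 0.5: no
#' remaining variant is more likely causal than not) or when no harvested
#' configuration supports the conditioning event. Step 2 builds one set per
#' key variant: variants are ranked by conditional inclusion probability
#' given the conditioning keys and added in decreasing order until the
#' cumulative conditional probability reaches `rho`; the key variant is
#' always a member. Ties break toward the lower variant index; duplicate
#' sets are deduplicated.
#'
#' @param reduced A [normalize_posterior()] result.
#' @param rho Target coverage level in (0, 1), default 0.95.
#' @param stop_threshold Key-variant selection stop threshold, default 0.5.
#' @param condition_on Either `"others"` (default: each key's set conditions
#'   on the other keys, since conditioning a variant's inclusion on itself is
#'   vacuous) or `"all"` (condition on every key including the set's own).
#' @return List of credible sets, each a list with `key_variant`, `members`
#'   (sorted integer indices), `rho`, and `mass` (achieved cumulative
#'   conditional probability). Empty list when no key variant qualifies.
#' @export
credible_sets <- function(reduced, rho = 0.95, stop_threshold = 0.5,
                          condition_on = c("others", "all")) {
  stopifnot(inherits(reduced, "reduced_config_set"))
  condition_on <- match.arg(condition_on)
  if (rho <= 0 || rho >= 1) stop("`rho` must be in (0, 1)")
  if (!length(reduced$posterior)) return(list())

  keys <- integer(0)
  repeat {
    q <- conditional_inclusion(reduced, keys)
    if (is.null(q)) break
    q[keys] <- -Inf
    best <- which.max(q)
    if (q[best] < stop_threshold) break
    keys <- c(keys, best)
    if (length(keys) >= reduced$m) break
  }
  if (!length(keys)) return(list())

  sets <- list()
  seen_keys <- character(0)
  for (v in keys) {
    given <- if (condition_on == "others") setdiff(keys, v) else keys
    q <- conditional_inclusion(reduced, given)
    if (is.null(q)) {
      members <- v
      mass <- NA_real_
    } else {
      cand <- setdiff(seq_len(reduced$m), given)
      ord <- cand[order(-q[cand], cand)]
      cum <- cumsum(q[ord])
      n_take <- if (any(cum >= rho)) which(cum >= rho)[1] else length(ord)
      members <- ord[seq_len(n_take)]
      mass <- cum[n_take]
      if (!(v %in% members)) members <- c(members, v)
      members <- sort(members)
    }
    key <- paste(members, collapse = ",")
    if (!key %in% seen_keys) {
      seen_keys <- c(seen_keys, key)
      sets[[length(sets) + 1L]] <- list(key_variant = v, members = members,
                                        rho = rho, mass = mass)
    }
  }
  sets
}

#' Fine-map a locus end to end
#'
#' Convenience wrapper running [fit_finemap()], [normalize_posterior()],
#' [compute_pips()], and [credible_sets()].
#'
#' @param summary A [summary_input()] object.
#' @param hyper A [model_hyper()] object.
#' @param train A [train_config()] object.
#' @param rho Credible-set coverage level, default 0.95.
#' @param ... Passed to [credible_sets()].
#' @return An object of class `"finemap_result"` with `pips`,
#'   `credible_sets`, `reduced` (the normalized reduced configuration set),
#'   `probs` (final proposal probability map), `trace` (training loss), and
#'   `summary` metadata (m, n, variant ids).
#' @export
finemap_locus <- function(summary, hyper = model_hyper(),
                          train = train_config(), rho = 0.95, ...) {
  fit <- fit_finemap(summary, hyper = hyper, train = train)
  reduced <- normalize_posterior(fit$harvest, summary, hyper)
  pips <- compute_pips(reduced)
  sets <- credible_sets(reduced, rho = rho, ...)
  structure(list(pips = pips, credible_sets = sets, reduced = reduced,
                 probs = fit$probs, trace = fit$trace,
                 variant_ids = summary$variant_ids, m = summary$m,
                 n_samples = summary$n_samples, rho = rho),
            class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("finemap_result: %d variants, %d credible set(s) at rho = %.2f\n",
              x$m, length(x$credible_sets), x$rho))
  top <- order(x$pips, decreasing = TRUE)[seq_len(min(5, x$m))]
  cat("  top PIPs:\n")
  for (i in top) {
    id <- if (is.null(x$variant_ids)) as.character(i) else x$variant_ids[i]
    cat(sprintf("    %s  %.4f\n", id, x$pips[i]))
  }
  for (s in x$credible_sets) {
    cat(sprintf("  CS(key %d): {%s}\n", s$key_variant,
                paste(s$members, collapse = ", ")))
  }
  invisible(x)
}
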