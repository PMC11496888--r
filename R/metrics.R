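#' Area under the precision-recall curve for PIPs
#'
#' Sweeps a threshold over the PIPs (tied values grouped at one threshold)
#' and integrates precision over recall step-wise: precision is held at its
#' value at each achieved recall, which avoids the optimistic bias of linear
#' PR interpolation.
#'
#' @param pips Numeric score vector.
#' @param truth Binary vector (1 = causal) of the same length.
#' @return Scalar AUPRC in \[prevalence, 1\].
#' @export
auprc <- function(pips, truth) {
  truth <- as.integer(truth)
  if (length(pips) != length(truth)) stop("length mismatch")
  n_pos <- sum(truth)
  if (n_pos == 0L) stop("`truth` has no causal variant: recall undefined")
  ord <- order(pips, decreasing = TRUE)
  s <- pips[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Coverage, power, and mean size of credible sets
#'
#' Coverage is the fraction of reported sets containing at least one causal
#' variant; power is the fraction of causal variants captured by the union
#' of all sets; mean size is the average set cardinality.
#'
#' @param sets List of integer variant-index vectors (or the `credible_sets`
#'   element of a [finemap_locus()] result).
#' @param truth Binary causal indicator vector.
#' @return List with `coverage` (NA when no sets), `power`, `mean_size`,
#'   `n_sets`.
#' @export
credible_set_metrics <- function(sets, truth) {
  truth <- as.integer(truth)
  members <- lapply(sets, function(s) if (is.list(s)) s$members else as.integer(s))
  causal <- which(truth == 1L)
  if (!length(members)) {
    return(list(coverage = NA_real_, power = 0, mean_size = 0, n_sets = 0L))
  }
  hit <- vapply(members, function(s) any(s %in% causal), logical(1))
  union_all <- unique(unlist(members))
  list(coverage = mean(hit),
       power = if (length(causal)) mean(causal %in% union_all) else NA_real_,
       mean_size = mean(lengths(members)),
       n_sets = length(members))
}

#' Power versus FDR curve from PIPs
#'
#' For each distinct PIP threshold (descending), classifies variants with
#' PIP at or above the threshold as causal calls and reports the false
#' discovery rate `FP / (TP + FP)` and power `TP / (TP + FN)`.
#'
#' @inheritParams auprc
#' @return Data frame with columns `threshold`, `fdr`, `power`, sorted by
#'   descending threshold.
#' @export
power_fdr_curve <- function(pips, truth) {
  truth <- as.integer(truth)
  if (length(pips) != length(truth)) stop("length mismatch")
  n_pos <- sum(truth)
  if (n_pos == 0L) stop("`truth` has no causal variant")
  ord <- order(pips, decreasing = TRUE)
  s <- pips[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = s[last],
             fdr = fp[last] / (tp[last] + fp[last]),
             power = tp[last] / n_pos)
}

#' Evaluate one fine-mapping result against simulation truth
#'
#' @param result A [finemap_locus()] result (or a list with `pips` and
#'   `credible_sets`).
#' @param truth Binary causal indicator vector.
#' @return List of class `"eval_result"`: `auprc`, `coverage`, `power`,
#'   `mean_set_size`, `n_sets`, plus the `power_fdr` curve.
#' @export
evaluate_result <- function(result, truth) {
  cs <- credible_set_metrics(result$credible_sets, truth)
  structure(list(auprc = auprc(result$pips, truth),
                 coverage = cs$coverage, power = cs$power,
                 mean_set_size = cs$mean_size, n_sets = cs$n_sets,
                 power_fdr = power_fdr_curve(result$pips, truth)),
            class = "eval_result")
}

#' Aggregate per-replicate metrics with normal-approximation intervals
#'
#' @param values Numeric vector of per-replicate metric values (NAs dropped).
#' @param level Confidence level, default 0.95.
#' @return List with `mean`, `lower`, `upper`, `n`.
#' @export
aggregate_metric <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) return(list(mean = NA_real_, lower = NA_real_,
                           upper = NA_real_, n = 0L))
  mu <- mean(values)
  half <- if (n > 1L) stats::qnorm(1 - (1 - level) / 2) * stats::sd(values) / sqrt(n) else 0
  list(mean = mu, lower = mu - half, upper = mu + half, n = n)
}
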