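#' Run fine-mapping over a grid of simulated scenarios
#'
#' For each scenario: simulate a locus, fine-map it (training seeded from
#' the scenario seed so the whole run is reproducible), and evaluate PIPs
#' and credible sets against the simulation truth.
#'
#' @param scenarios List of [sim_scenario()] objects (see [scenario_grid()]).
#' @param hyper A [model_hyper()] object.
#' @param train A [train_config()] template; its seed is replaced per
#'   scenario by the scenario seed.
#' @param rho Credible-set coverage level.
#' @param verbose Print one line per scenario.
#' @return Data frame with one row per scenario: the scenario parameters and
#'   `auprc`, `coverage`, `power`, `mean_set_size`, `n_sets`, `top_pip_hit`
#'   (1 when the highest-PIP variant is causal).
#' @export
run_benchmark <- function(scenarios, hyper = model_hyper(),
                          train = train_config(), rho = 0.95,
                          verbose = FALSE) {
  rows <- lapply(scenarios, function(sc) {
    locus <- simulate_locus(sc)
    tr <- train
    tr$seed <- sc$seed
    res <- finemap_locus(locus$summary, hyper = hyper, train = tr, rho = rho)
    ev <- evaluate_result(res, locus$truth)
    top <- which.max(res$pips)
    if (verbose) {
      message(sprintf(
        "d=%d omega2=%.2f p=%.2f seed=%d: auprc=%.3f coverage=%s size=%.1f",
        sc$d, sc$omega2, sc$p_causal, sc$seed, ev$auprc,
        format(ev$coverage), ev$mean_set_size))
    }
    data.frame(m = sc$m, n = sc$n, d = sc$d, omega2 = sc$omega2,
               p_causal = sc$p_causal, seed = sc$seed,
               auprc = ev$auprc, coverage = ev$coverage, power = ev$power,
               mean_set_size = ev$mean_set_size, n_sets = ev$n_sets,
               top_pip_hit = as.integer(locus$truth[top] == 1L))
  })
  do.call(rbind, rows)
}
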