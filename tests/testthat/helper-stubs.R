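# deterministic stub batch runner: the CMR is reached iff rate >= threshold
step_stub <- function(threshold) {
  function(rate, cfg, n_runs, seeds, ...) {
    reached <- rate >= threshold
    tibble::tibble(
      mutation_rate = rate, runs_total = n_runs, runs_planned = n_runs,
      runs_lost = if (reached) n_runs else 0L,
      runs_kept = if (reached) 0L else n_runs,
      early_advanced = !reached, reached_cmr = reached
    )
  }
}

# stochastic stub: each run loses peak 0 independently with probability
# p(rate), a logistic in log10(rate)
logistic_stub <- function(mid, slope) {
  function(rate, cfg, n_runs, seeds, ...) {
    p <- stats::plogis((log10(rate) - mid) * slope)
    lost <- rbinom(1, n_runs, p)
    tibble::tibble(
      mutation_rate = rate, runs_total = n_runs, runs_planned = n_runs,
      runs_lost = lost, runs_kept = n_runs - lost,
      early_advanced = FALSE,
      reached_cmr = lost >= ceiling(0.95 * n_runs)
    )
  }
}

fake_cfg <- list(seed = 1L)
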