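#' Mutation-rate sweep grids
#'
#' The coarse grid steps the leading digit through each order of magnitude,
#' `d * 10^-e` for `d = 1..9` and `e = 8` down to `2`, ascending from
#' `1e-8` to `1e-2`; it locates the order of magnitude of the CMR. The fine
#' grid then increments by `0.1 * 10^-e` within one decade
#' (`1.0, 1.1, ..., 9.9 x 10^-e`) to pinpoint it.
#'
#' @param min_exp,max_exp Smallest and largest decades (as positive
#'   exponents of `10^-e`) spanned by the coarse grid.
#' @return Numeric vector of strictly ascending per-base mutation rates.
#' @examples
#' head(coarse_grid())
#' head(fine_grid(4))
#' @export
coarse_grid <- function(min_exp = 8L, max_exp = 2L) {
  stopifnot(min_exp > max_exp)
  rates <- as.vector(outer(1:9, 10^-(seq(min_exp, max_exp)), "*"))
  rates <- rates[rates <= 10^-max_exp]
  sort(unique(c(rates, 10^-max_exp)))
}

#' @rdname coarse_grid
#' @param decade Positive exponent `e` of the decade `[10^-e, 10^-(e-1))`.
#' @export
fine_grid <- function(decade) {
  stopifnot(decade >= 1)
  (10:99) / 10 * 10^-decade
}

#' Decade (positive exponent) containing a rate
#' @param rate Per-base mutation rate.
#' @return Integer `e` such that `rate` lies in `[10^-e, 10^-(e-1))`.
#' @export
decade_of <- function(rate) {
  as.integer(-floor(log10(rate) + 1e-12))
}

#' Derive per-run seeds from a master seed
#'
#' One independent seed per (batch, run) cell, a pure function of the master
#' seed. Reusing the matrix across mutation rates gives common random
#' numbers within a batch, which reduces the variance of batch-CMR
#' comparisons across rates.
#'
#' @param master Master integer seed.
#' @param n_batches,batch_size Matrix dimensions.
#' @return An `n_batches x batch_size` integer matrix of seeds.
#' @export
derive_seeds <- function(master, n_batches, batch_size) {
  set.seed(as.integer(master) %% .Machine$integer.max)
  matrix(sample.int(.Machine$integer.max - 1L, n_batches * batch_size),
         nrow = n_batches, ncol = batch_size)
}

#' Run a batch of simulations at one mutation rate
#'
#' Executes up to `n_runs` runs with distinct seeds and counts peak-0
#' losses. A rate is abandoned early ("early advance") as soon as the
#' keepers make a 95% loss fraction impossible: once
#' `floor(0.05 * n_runs) + 1` runs have kept peak 0, fewer than
#' `ceiling(0.95 * n_runs)` losses remain achievable, so the accept/reject
#' decision at the rate is already fixed.
#'
#' @param rate Per-base mutation rate for every run in the batch.
#' @param cfg A [run_config()] (its `mutation_rate` is overridden by
#'   `rate`, its seed by the entries of `seeds`).
#' @param n_runs Planned number of runs.
#' @param seeds Optional integer vector of per-run seeds (recycled seeds
#'   are derived from `cfg$seed` when omitted).
#' @param keeper_threshold Keepers triggering early advance.
#' @param loss_threshold Losses required to declare the CMR reached.
#' @return A one-row tibble: `mutation_rate`, `runs_total` (executed),
#'   `runs_planned`, `runs_lost`, `runs_kept`, `early_advanced`,
#'   `reached_cmr`.
#' @export
run_batch <- function(rate, cfg, n_runs = 100, seeds = NULL,
                      keeper_threshold = floor(0.05 * n_runs) + 1,
                      loss_threshold = ceiling(0.95 * n_runs)) {
  stopifnot(n_runs >= 1)
  if (is.null(seeds)) {
    seeds <- derive_seeds(cfg$seed, 1L, n_runs)[1L, ]
  }
  stopifnot(length(seeds) >= n_runs)
  rep2 <- cfg$reproduction
  rep2$mutation_rate <- rate
  lost <- 0L
  kept <- 0L
  ran <- 0L
  early <- FALSE
  for (i in seq_len(n_runs)) {
    ci <- cfg
    ci$reproduction <- rep2
    ci$seed <- seeds[i]
    r <- run_simulation(ci)
    ran <- ran + 1L
    if (r$lost_peak0) lost <- lost + 1L else kept <- kept + 1L
    if (kept >= keeper_threshold) {
      early <- TRUE
      break
    }
  }
  tibble::tibble(
    mutation_rate = rate, runs_total = ran, runs_planned = n_runs,
    runs_lost = lost, runs_kept = kept, early_advanced = early,
    reached_cmr = lost >= loss_threshold
  )
}

#' Locate the order of magnitude of the CMR
#'
#' Ascends the coarse grid, running a batch at each rate (abandoning rates
#' early once enough runs keep peak 0), and returns the decade of the first
#' rate at which the loss fraction reaches 95%.
#'
#' @inheritParams run_batch
#' @param grid Ascending rate grid (default [coarse_grid()]).
#' @param runner Batch runner with the [run_batch()] signature
#'   `(rate, cfg, n_runs, seeds)`; substitute a stub for protocol tests.
#' @return A list: `found`, `rate`, `decade`, and `results` (one row per
#'   rate tried).
#' @export
coarse_sweep <- function(cfg, n_runs = 100, grid = coarse_grid(),
                         runner = run_batch, seeds = NULL) {
  if (is.null(seeds)) seeds <- derive_seeds(cfg$seed, 1L, n_runs)[1L, ]
  rows <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    b <- runner(grid[j], cfg, n_runs, seeds)
    rows[[j]] <- b
    if (isTRUE(b$reached_cmr)) {
      return(list(found = TRUE, rate = grid[j], decade = decade_of(grid[j]),
                  results = dplyr::bind_rows(rows[seq_len(j)])))
    }
  }
  list(found = FALSE, rate = NA_real_, decade = NA_integer_,
       results = dplyr::bind_rows(rows))
}

# smallest rate of `grid` at which the batch reaches the loss threshold
batch_cmr_on_grid <- function(cfg, grid, batch_size, seeds_row, runner) {
  for (rate in grid) {
    b <- runner(rate, cfg, batch_size, seeds_row)
    if (isTRUE(b$reached_cmr)) return(rate)
  }
  NA_real_
}

#' Pinpoint the CMR within a decade, batch by batch
#'
#' For each batch, ascends the fine grid of the decade found by
#' [coarse_sweep()]; the batch CMR is the smallest rate at which at least
#' 95% of that batch's runs lose peak 0. If no rate in the decade reaches
#' the threshold the batch escalates to the next (larger-rate) decade, down
#' to `min_decade`; a batch that never reaches it is censored (`NA`). The
#' batch values yield the headline mean, SD and 95% Student-t confidence
#' interval (batches - 1 degrees of freedom).
#'
#' @inheritParams coarse_sweep
#' @param decade Decade (positive exponent) from [coarse_sweep()].
#' @param n_batches,batch_size Batches of runs (full protocol: 20 x 100).
#' @param min_decade Largest rate decade a batch may escalate into.
#' @param seeds Optional `n_batches x batch_size` seed matrix; rows are
#'   reused across rates (common random numbers).
#' @return A `cmr_estimate` object; see [tidy.cmr_estimate()] and
#'   [glance.cmr_estimate()].
#' @export
fine_sweep <- function(cfg, decade, n_batches = 20, batch_size = 100,
                       runner = run_batch, seeds = NULL, min_decade = 2L) {
  if (is.null(seeds)) seeds <- derive_seeds(cfg$seed, n_batches, batch_size)
  vals <- vapply(seq_len(n_batches), function(b) {
    dec <- decade
    while (dec >= min_decade) {
      v <- batch_cmr_on_grid(cfg, fine_grid(dec), batch_size,
                             seeds[b, ], runner)
      if (!is.na(v)) return(v)
      dec <- dec - 1L
    }
    NA_real_
  }, numeric(1))
  new_cmr_estimate(vals, batch_size = batch_size,
                   protocol = "fine", decade = decade)
}

new_cmr_estimate <- function(batch_cmrs, batch_size, protocol,
                             decade = NA_integer_, config_summary = NULL) {
  ok <- !is.na(batch_cmrs)
  k <- sum(ok)
  m <- if (k > 0) mean(batch_cmrs[ok]) else NA_real_
  s <- if (k > 1) stats::sd(batch_cmrs[ok]) else NA_real_
  half <- if (k > 1) qt(0.975, k - 1) * s / sqrt(k) else NA_real_
  structure(
    list(batch_cmrs = batch_cmrs, mean = m, sd = s,
         ci95 = c(low = m - half, high = m + half),
         n_batches = length(batch_cmrs), batch_size = batch_size,
         n_censored = sum(!ok), protocol = protocol, decade = decade,
         config_summary = config_summary),
    class = "cmr_estimate"
  )
}

#' @export
print.cmr_estimate <- function(x, ...) {
  cat("<cmr_estimate> ", x$n_batches, " batches x ", x$batch_size,
      " runs (", x$protocol, " grid)\n", sep = "")
  cat(sprintf("  CMR mean %.4g  sd %.3g  95%% CI [%.4g, %.4g]",
              x$mean, x$sd, x$ci95[["low"]], x$ci95[["high"]]), "\n")
  if (x$n_censored > 0) {
    cat("  ", x$n_censored, " batch(es) censored above the grid\n", sep = "")
  }
  invisible(x)
}

#' Tidy a CMR estimate into one row per batch
#' @param x A `cmr_estimate`.
#' @param ... Unused.
#' @return A tibble with `batch`, `cmr` and `censored`.
#' @exportS3Method generics::tidy
tidy.cmr_estimate <- function(x, ...) {
  tibble::tibble(batch = seq_along(x$batch_cmrs), cmr = x$batch_cmrs,
                 censored = is.na(x$batch_cmrs))
}

#' One-row summary of a CMR estimate
#' @param x A `cmr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the mean, SD, CI bounds and protocol sizes.
#' @exportS3Method generics::glance
glance.cmr_estimate <- function(x, ...) {
  tibble::tibble(
    cmr_mean = x$mean, cmr_sd = x$sd,
    ci_low = x$ci95[["low"]], ci_high = x$ci95[["high"]],
    n_batches = x$n_batches, batch_size = x$batch_size,
    n_censored = x$n_censored
  )
}

#' Per-batch CMR values with a censoring policy
#'
#' Batches whose CMR lies above the top of the sweep grid are stored as
#' `NA`. For directional comparisons it is conservative to substitute the
#' grid top (the true value is at least that large).
#'
#' @param est A `cmr_estimate`.
#' @param censored `"na"` keeps censored batches as `NA`; `"grid_top"`
#'   substitutes `grid_top`.
#' @param grid_top Substitution value for censored batches.
#' @return Numeric vector of batch CMRs.
#' @export
cmr_values <- function(est, censored = c("na", "grid_top"),
                       grid_top = 1e-2) {
  censored <- match.arg(censored)
  v <- est$batch_cmrs
  if (censored == "grid_top") v[is.na(v)] <- grid_top
  v
}

#' Estimate the critical mutation rate for one parameter combination
#'
#' The full protocol first identifies the decade of the CMR with a coarse
#' sweep, then pinpoints it per batch on the fine grid ([fine_sweep()]).
#' The reduced protocol (`protocol = "coarse"`) scores each batch directly
#' on the coarse grid — the batch CMR is then the smallest coarse rate with
#' at least 95% losses — trading resolution for run time.
#'
#' @inheritParams fine_sweep
#' @param protocol `"fine"` (coarse sweep then fine grid, the full
#'   protocol) or `"coarse"` (coarse grid only).
#' @param grid Grid used per batch under `protocol = "coarse"`.
#' @return A `cmr_estimate`.
#' @export
estimate_cmr <- function(cfg, n_batches = 20, batch_size = 100,
                         protocol = c("fine", "coarse"),
                         grid = coarse_grid(), runner = run_batch,
                         seeds = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(seeds)) seeds <- derive_seeds(cfg$seed, n_batches, batch_size)
  if (protocol == "coarse") {
    vals <- vapply(seq_len(n_batches), function(b) {
      batch_cmr_on_grid(cfg, grid, batch_size, seeds[b, ], runner)
    }, numeric(1))
    return(new_cmr_estimate(vals, batch_size = batch_size,
                            protocol = "coarse"))
  }
  cs <- coarse_sweep(cfg, n_runs = batch_size, grid = grid,
                     runner = runner, seeds = seeds[1L, ])
  if (!cs$found) {
    return(new_cmr_estimate(rep(NA_real_, n_batches),
                            batch_size = batch_size, protocol = "fine"))
  }
  fine_sweep(cfg, cs$decade, n_batches = n_batches,
             batch_size = batch_size, runner = runner, seeds = seeds)
}
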