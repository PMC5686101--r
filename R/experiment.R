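#' Build and validate an experiment configuration
#'
#' One configuration drives a whole CMR experiment: the landscape geometry,
#' reproduction parameters, the population sizes to sweep, an optional
#' covariate sweep (gene length, gene count, scale, crossovers or
#' chromosomes), the estimation protocol sizes and the master seed.
#' Defaults are the canonical setting: one 1,000 bp gene, radii 2 and 5,
#' inter-peak distance 10, scale 1, one crossover, one chromosome,
#' `lambda = 0.999999999999999`, heights 15 and 10.
#'
#' @param file Optional YAML file of configuration keys; values passed via
#'   `...` override the file.
#' @param ... Configuration keys (see Details).
#' @param profile `"full"` (10,000 generations, 20 batches x 100 runs,
#'   coarse + fine grid — the publication protocol) or `"reduced"` (2,000
#'   generations, 5 batches x 20 runs, coarse grid only — a desk-scale
#'   protocol for trend studies). Explicit keys override profile defaults.
#'
#' @details Recognised keys: `gene_length`, `gene_count`, `r0`, `r1`,
#' `distance`, `scale`, `h0`, `h1`, `crossovers`, `chromosomes`, `lambda`,
#' `population_sizes` (vector), `max_generations`, `n_batches`,
#' `batch_size`, `protocol` (`"fine"`/`"coarse"`), `sweep` (a list with
#' `covariate` and `values`), `seed`.
#'
#' @return A validated `cmr_experiment_config` list.
#' @examples
#' cfg <- experiment_config(profile = "reduced", gene_length = 30,
#'                          population_sizes = c(10, 20), seed = 1)
#' @export
experiment_config <- function(file = NULL, ..., profile = c("full",
                                                            "reduced")) {
  profile <- match.arg(profile)
  defaults <- list(
    gene_length = 1000L, gene_count = 1L, r0 = 2, r1 = 5, distance = 10,
    scale = 1L, h0 = 15, h1 = 10, crossovers = 1L, chromosomes = 1L,
    lambda = 0.999999999999999, population_sizes = c(10L),
    max_generations = if (profile == "full") 10000L else 2000L,
    n_batches = if (profile == "full") 20L else 5L,
    batch_size = if (profile == "full") 100L else 20L,
    protocol = if (profile == "full") "fine" else "coarse",
    sweep = list(covariate = "none", values = NA),
    seed = 1L
  )
  from_file <- if (!is.null(file)) yaml::read_yaml(file) else list()
  user <- modifyList(from_file, list(...))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, user)
  cfg$profile <- profile
  validate_experiment_config(cfg)
  structure(cfg, class = "cmr_experiment_config")
}

validate_experiment_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, key) if (!isTRUE(all(ok))) bad <<- c(bad, key)
  chk(cfg$gene_length >= 1, "gene_length")
  chk(cfg$gene_count >= 1, "gene_count")
  chk(cfg$r0 >= 1, "r0")
  chk(cfg$r1 >= 1, "r1")
  chk(cfg$distance > cfg$r0 + cfg$r1, "distance")
  chk(cfg$scale >= 1, "scale")
  chk(cfg$scale * cfg$distance <= cfg$gene_length, "scale")
  chk(cfg$h0 > cfg$h1 && cfg$h1 > 0, "h0")
  chk(cfg$lambda >= 0 && cfg$lambda <= 1, "lambda")
  chk(all(cfg$population_sizes >= 1), "population_sizes")
  chk(cfg$max_generations >= 1, "max_generations")
  chk(cfg$n_batches >= 1, "n_batches")
  chk(cfg$batch_size >= 1, "batch_size")
  chk(cfg$protocol %in% c("fine", "coarse"), "protocol")
  chk(cfg$sweep$covariate %in% c("none", "gene_length", "gene_count",
                                 "scale", "crossovers", "chromosomes"),
      "sweep")
  bl <- min_block_length(cfg$gene_length, cfg$chromosomes)
  chk(cfg$crossovers >= 1 && cfg$crossovers <= bl - 1, "crossovers")
  if (length(bad) > 0) {
    stop("invalid experiment configuration; offending key(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(cfg)
}

# materialise one experiment cell as a run_config
cell_run_config <- function(cfg, covariate, value, N, seed) {
  p <- cfg
  if (covariate != "none") p[[covariate]] <- value
  land <- make_landscape(n = p$gene_count, L = p$gene_length, r0 = p$r0,
                         r1 = p$r1, D = p$distance, S = p$scale,
                         h0 = p$h0, h1 = p$h1, seed = seed)
  run_config(
    land, population_size = N,
    reproduction = reproduction_config(
      crossovers = p$crossovers, chromosomes = p$chromosomes,
      lambda = p$lambda
    ),
    max_generations = p$max_generations, seed = seed
  )
}

#' Run a full CMR experiment to result files
#'
#' Estimates the CMR for every (covariate value, population size) cell of
#' the configuration and writes: one per-batch CSV per cell under
#' `cells/`, a `summary.csv` with one row per cell (mean, SD, 95% CI,
#' censored batch count), and a `manifest.json` capturing the full
#' configuration, the derived per-cell seeds and the package version.
#' Re-running with the same configuration and output directory reproduces
#' identical outputs; completed cells are detected by their files and
#' skipped, so an interrupted experiment resumes where it stopped.
#'
#' @param config A [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Recompute cells whose files already exist.
#' @param quiet Suppress per-cell progress messages.
#' @return The summary tibble, invisibly.
#' @export
run_experiment <- function(config, out_dir, overwrite = FALSE,
                           quiet = FALSE) {
  stopifnot(inherits(config, "cmr_experiment_config"))
  dir.create(file.path(out_dir, "cells"), recursive = TRUE,
             showWarnings = FALSE)
  covariate <- config$sweep$covariate
  values <- if (covariate == "none") NA else config$sweep$values
  cells <- expand.grid(value = values, N = config$population_sizes,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(config$seed, 1L, nrow(cells))[1L, ]
  summary_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    value <- cells$value[i]
    N <- cells$N[i]
    tag <- if (covariate == "none") sprintf("base_N%d", N) else
      sprintf("%s%s_N%d", covariate, format(value), N)
    cell_file <- file.path(out_dir, "cells", paste0(tag, ".csv"))
    if (file.exists(cell_file) && !overwrite) {
      if (!quiet) message("cell ", tag, ": found, skipping")
      batches <- tibble::as_tibble(read.csv(cell_file))
      est <- new_cmr_estimate(batches$cmr, batch_size = config$batch_size,
                              protocol = config$protocol)
    } else {
      if (!quiet) {
        message("cell ", tag, ": estimating CMR (", config$n_batches,
                " batches x ", config$batch_size, " runs)")
      }
      rc <- cell_run_config(config, covariate, value, N, cell_seeds[i])
      est <- estimate_cmr(rc, n_batches = config$n_batches,
                          batch_size = config$batch_size,
                          protocol = config$protocol)
      write.csv(tidy(est), cell_file, row.names = FALSE)
    }
    g <- glance(est)
    g$covariate <- covariate
    g$value <- value
    g$N <- N
    summary_rows[[i]] <- g
  }
  summary <- dplyr::bind_rows(summary_rows) |>
    dplyr::select("covariate", "value", "N", dplyr::everything())
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  manifest <- list(
    package = "cmrsim",
    version = as.character(utils::packageVersion("cmrsim")),
    config = unclass(config),
    cell_seeds = cell_seeds,
    cells = cells
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
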