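#' Configuration of a single simulation run
#'
#' @param landscape A [make_landscape()] object.
#' @param population_size Number of diploid individuals `N`.
#' @param reproduction A [reproduction_config()].
#' @param max_generations Generation cap (default 10,000: a run that retains
#'   peak 0 this long is scored as having kept it).
#' @param seed Integer seed making the run fully reproducible.
#' @return A `cmr_run_config` list.
#' @export
run_config <- function(landscape, population_size,
                       reproduction = reproduction_config(),
                       max_generations = 10000L, seed = 1L) {
  stopifnot(inherits(landscape, "cmr_landscape"),
            population_size >= 1, max_generations >= 1)
  check_crossovers(landscape, reproduction)
  structure(
    list(landscape = landscape,
         population_size = as.integer(population_size),
         reproduction = reproduction,
         max_generations = as.integer(max_generations),
         seed = as.integer(seed)),
    class = "cmr_run_config"
  )
}

land_args <- function(landscape, lambda) {
  list(t0 = landscape$t0, t1 = landscape$t1,
       h0 = landscape$heights[["h0"]], h1 = landscape$heights[["h1"]],
       r0 = landscape$radius0, r1 = landscape$radius1, lambda = lambda)
}

#' Triple-tournament replacement
#'
#' The three indexed individuals are ranked by fitness (ties broken
#' uniformly at random); the least fit is replaced with probability 0.5 and
#' each of the two fitter with probability 0.25 — so even the fittest can be
#' replaced, which is what makes loss of the fitter peak possible. The two
#' survivors parent the child that fills the vacated slot.
#'
#' @param pop A `cmr_population`.
#' @param indices Three distinct individual indices.
#' @param cfg A [reproduction_config()].
#' @return A list with the updated `population` and the `replaced` index.
#' @export
tournament_replace <- function(pop, indices, cfg = reproduction_config()) {
  stopifnot(length(indices) == 3, !anyDuplicated(indices))
  land <- pop$landscape
  check_crossovers(land, cfg)
  mat <- pop$maternal + 0L # force copies: cpp works in place
  pat <- pop$paternal + 0L
  la <- land_args(land, cfg$lambda)
  fit <- cpp_population_fitness(mat, pat, la$t0, la$t1, la$h0, la$h1,
                                la$r0, la$r1, la$lambda)
  replaced <- cpp_tournament(mat, pat, fit, as.integer(indices),
                             la$t0, la$t1, la$h0, la$h1, la$r0, la$r1,
                             la$lambda, cfg$mutation_rate, cfg$crossovers,
                             cfg$chromosomes)
  pop$maternal <- mat
  pop$paternal <- pat
  list(population = pop, replaced = replaced)
}

#' Advance a population by one discrete generation
#'
#' A uniform random permutation of the population is cut into consecutive
#' disjoint triples and [tournament_replace()] is applied to each, so every
#' individual is chosen at most once per generation; the `N mod 3` leftover
#' individuals pass through unchanged. Population size is conserved.
#'
#' @inheritParams tournament_replace
#' @return The updated `cmr_population`.
#' @export
run_generation <- function(pop, cfg = reproduction_config()) {
  land <- pop$landscape
  check_crossovers(land, cfg)
  mat <- pop$maternal + 0L
  pat <- pop$paternal + 0L
  la <- land_args(land, cfg$lambda)
  fit <- cpp_population_fitness(mat, pat, la$t0, la$t1, la$h0, la$h1,
                                la$r0, la$r1, la$lambda)
  cpp_run_generation(mat, pat, fit, la$t0, la$t1, la$h0, la$h1, la$r0,
                     la$r1, la$lambda, cfg$mutation_rate, cfg$crossovers,
                     cfg$chromosomes)
  pop$maternal <- mat
  pop$paternal <- pat
  pop
}

#' Does any individual still carry peak 0 at a gene?
#'
#' Peak 0 is "present" at gene `g` while some individual has a maternal or
#' paternal gene-`g` segment strictly within the peak-0 radius of the
#' gene's peak-0 target (distance `< r0`: the radius itself is the point of
#' zero fitness).
#'
#' @param pop A `cmr_population`.
#' @param gene Gene index (1-based), or `NULL` to check every gene.
#' @return Logical (scalar for one gene, vector over genes for `NULL`).
#' @export
peak0_present <- function(pop, gene = NULL) {
  land <- pop$landscape
  genes <- if (is.null(gene)) seq_len(land$gene_count) else gene
  vapply(genes, function(g) {
    stopifnot(g >= 1, g <= land$gene_count)
    t0g <- land$t0[, g, drop = FALSE]
    rows <- ((g - 1) * land$gene_length + 1):(g * land$gene_length)
    cpp_first_lost_gene(pop$maternal[rows, , drop = FALSE],
                        pop$paternal[rows, , drop = FALSE],
                        t0g, land$radius0) == 0L
  }, logical(1))
}

#' Run one simulation to peak-0 loss or the generation cap
#'
#' Initialises the population half-and-half on the two peak tops, then
#' iterates discrete generations; after each generation every gene is
#' checked for loss of peak 0, and the run stops at the first generation
#' where any gene has lost it (recording the generation and the gene) or at
#' `max_generations`. Results are a pure function of the configuration,
#' including the seed.
#'
#' @param cfg A [run_config()].
#' @param engine `"compiled"` runs the whole loop in C++; `"r"` drives the
#'   identical per-generation kernel from R (same random stream, same
#'   result; useful for instrumentation).
#' @param trace Optional path to a CSV trace written one row per generation
#'   (generation, per-gene peak-0 carrier counts, mean and max fitness);
#'   only available with `engine = "r"`.
#' @return A one-row tibble: `lost_peak0`, `loss_generation`, `lost_gene`,
#'   `generations_run`, `seed`.
#' @examples
#' land <- make_landscape(L = 30, seed = 1)
#' cfg <- run_config(land, population_size = 10,
#'                   reproduction = reproduction_config(mutation_rate = 0.05),
#'                   max_generations = 200, seed = 42)
#' run_simulation(cfg)
#' @export
run_simulation <- function(cfg, engine = c("compiled", "r"), trace = NULL) {
  engine <- match.arg(engine)
  land <- cfg$landscape
  rep <- cfg$reproduction
  set.seed(cfg$seed)
  pop <- initialize_population(cfg$population_size, land)
  mat <- pop$maternal + 0L
  pat <- pop$paternal + 0L
  la <- land_args(land, rep$lambda)
  fit <- cpp_population_fitness(mat, pat, la$t0, la$t1, la$h0, la$h1,
                                la$r0, la$r1, la$lambda)
  if (engine == "compiled") {
    res <- cpp_run_simulation(mat, pat, fit, la$t0, la$t1, la$h0, la$h1,
                              la$r0, la$r1, la$lambda, rep$mutation_rate,
                              rep$crossovers, rep$chromosomes,
                              cfg$max_generations)
    lost <- res$lost
    gen <- res$generation
    gene <- res$gene
  } else {
    lost <- FALSE
    gene <- NA_integer_
    gen <- cfg$max_generations
    con <- if (!is.null(trace)) file(trace, "w")
    if (!is.null(trace)) {
      writeLines(paste(c("generation",
                         paste0("carriers_gene", seq_len(land$gene_count)),
                         "mean_fitness", "max_fitness"), collapse = ","),
                 con)
    }
    for (g in seq_len(cfg$max_generations)) {
      cpp_run_generation(mat, pat, fit, la$t0, la$t1, la$h0, la$h1, la$r0,
                         la$r1, la$lambda, rep$mutation_rate,
                         rep$crossovers, rep$chromosomes)
      if (!is.null(trace)) {
        carr <- vapply(seq_len(land$gene_count), function(gg) {
          rows <- ((gg - 1) * land$gene_length + 1):(gg * land$gene_length)
          sum(colSums(mat[rows, , drop = FALSE] != land$t0[, gg]) <
                land$radius0 |
              colSums(pat[rows, , drop = FALSE] != land$t0[, gg]) <
                land$radius0)
        }, integer(1))
        writeLines(paste(c(g, carr, mean(fit), max(fit)), collapse = ","),
                   con)
      }
      lost_gene <- cpp_first_lost_gene(mat, pat, la$t0, la$r0)
      if (lost_gene > 0L) {
        lost <- TRUE
        gene <- lost_gene
        gen <- g
        break
      }
    }
    if (!is.null(trace)) close(con)
  }
  tibble::tibble(
    lost_peak0 = lost,
    loss_generation = if (lost) as.integer(gen) else NA_integer_,
    lost_gene = if (lost) as.integer(gene) else NA_integer_,
    generations_run = as.integer(gen),
    seed = cfg$seed
  )
}
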