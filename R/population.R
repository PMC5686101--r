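#' Create a diploid individual
#'
#' @param maternal,paternal Integer vectors over `0:3` of identical length
#'   `n * L` (the concatenated gene segments).
#' @return A `cmr_individual` list.
#' @export
new_individual <- function(maternal, paternal) {
  maternal <- as.integer(maternal)
  paternal <- as.integer(paternal)
  stopifnot(length(maternal) == length(paternal),
            all(maternal %in% 0:3), all(paternal %in% 0:3))
  structure(list(maternal = maternal, paternal = paternal),
            class = "cmr_individual")
}

#' Reproduction parameters
#'
#' @param mutation_rate Per-base mutation probability `M` applied to each
#'   child strand (per gene: the number of mutated positions is drawn from
#'   `Binomial(L, M)`).
#' @param crossovers Crossover events `k` per chromosome per gamete.
#' @param chromosomes Chromosomes `c` each gene is split into (contiguous
#'   equal blocks; the last block absorbs any remainder).
#' @param lambda Dominance weight combining the fitter and less fit allele.
#' @return A `cmr_reproduction` list.
#' @export
reproduction_config <- function(mutation_rate = 0, crossovers = 1L,
                                chromosomes = 1L,
                                lambda = 0.999999999999999) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            crossovers >= 1, chromosomes >= 1,
            lambda >= 0, lambda <= 1)
  structure(
    list(mutation_rate = mutation_rate,
         crossovers = as.integer(crossovers),
         chromosomes = as.integer(chromosomes),
         lambda = lambda),
    class = "cmr_reproduction"
  )
}

# smallest chromosome block length for a gene of length L split into c blocks
min_block_length <- function(L, c) {
  base <- L %/% c
  if (c == 1) L else min(base, L - base * (c - 1))
}

check_crossovers <- function(landscape, cfg) {
  bl <- min_block_length(landscape$gene_length, cfg$chromosomes)
  if (cfg$crossovers > bl - 1) {
    stop("crossovers (", cfg$crossovers, ") exceed the internal boundaries ",
         "of the shortest chromosome block (length ", bl, ")")
  }
  invisible(TRUE)
}

#' Initialise a population split across the two peak tops
#'
#' The starting condition of every run: `ceiling(N/2)` individuals sit with
#' both strands on the concatenated peak-0 targets and `floor(N/2)` on the
#' peak-1 targets (the odd individual goes to the fitter peak 0), in
#' shuffled order.
#'
#' @param N Population size (constant across generations).
#' @param landscape A [make_landscape()] object.
#' @param shuffle Shuffle the member order (default `TRUE`).
#' @return A `cmr_population`: genome matrices `maternal` and `paternal`
#'   (`n*L` rows, `N` columns) plus the landscape.
#' @export
initialize_population <- function(N, landscape, shuffle = TRUE) {
  stopifnot(N >= 1)
  N <- as.integer(N)
  g0 <- as.vector(landscape$t0)
  g1 <- as.vector(landscape$t1)
  n0 <- ceiling(N / 2)
  genomes <- cbind(
    matrix(g0, nrow = length(g0), ncol = n0),
    if (N - n0 > 0) matrix(g1, nrow = length(g1), ncol = N - n0)
  )
  if (shuffle) genomes <- genomes[, sample.int(N), drop = FALSE]
  storage.mode(genomes) <- "integer"
  structure(
    list(maternal = genomes, paternal = genomes, landscape = landscape),
    class = "cmr_population"
  )
}

#' @export
print.cmr_population <- function(x, ...) {
  cat("<cmr_population> N =", ncol(x$maternal), "diploid individuals,",
      nrow(x$maternal), "bp genomes\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `cmr_population`.
#' @return Integer population size.
#' @export
population_size <- function(pop) ncol(pop$maternal)

#' Extract one individual from a population
#' @param pop A `cmr_population`.
#' @param i Individual index.
#' @return A `cmr_individual`.
#' @export
get_individual <- function(pop, i) {
  new_individual(pop$maternal[, i], pop$paternal[, i])
}

#' Mutate a sequence at a per-base rate
#'
#' Draws `K ~ Binomial(length(seq), M)`, samples `K` distinct positions
#' uniformly, and sets each to one of the three other symbols with equal
#' probability, so exactly `K` positions differ from the input.
#'
#' @param seq Integer vector over `0:3`.
#' @param M Per-base mutation probability.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, M) {
  stopifnot(M >= 0, M <= 1)
  cpp_mutate(as.integer(seq), M)
}

#' Form a gamete from a diploid parent
#'
#' Meiosis-style recombination: the genome is partitioned into `n * c`
#' chromosomes (each gene split into `c` contiguous blocks, the last block
#' absorbing any length remainder). For each chromosome independently a
#' starting strand is chosen uniformly (independent assortment) and `k`
#' distinct crossover points are placed uniformly among its internal
#' boundaries; the output alternates source strand at each point, so every
#' position of the gamete comes from one of the two parental strands.
#'
#' @param parent A `cmr_individual`.
#' @param landscape A [make_landscape()] object.
#' @param crossovers Crossovers `k` per chromosome.
#' @param chromosomes Chromosomes `c` per gene.
#' @return Integer vector of length `n * L`.
#' @export
make_gamete <- function(parent, landscape, crossovers = 1L,
                        chromosomes = 1L) {
  cfg <- reproduction_config(crossovers = crossovers,
                             chromosomes = chromosomes)
  check_crossovers(landscape, cfg)
  cpp_make_gamete(as.integer(parent$maternal), as.integer(parent$paternal),
                  landscape$gene_count, landscape$gene_length,
                  cfg$chromosomes, cfg$crossovers)
}

#' Produce a child from two parents
#'
#' The child's maternal strand is a mutated gamete of `parentA`, its
#' paternal strand a mutated gamete of `parentB`; mutation is applied
#' independently per strand and per gene segment (`L` binomial trials each).
#'
#' @param parentA,parentB `cmr_individual` parents.
#' @param cfg A [reproduction_config()].
#' @param landscape A [make_landscape()] object.
#' @return A `cmr_individual` child.
#' @export
reproduce <- function(parentA, parentB, cfg, landscape) {
  check_crossovers(landscape, cfg)
  n <- landscape$gene_count
  L <- landscape$gene_length
  gm <- cpp_make_gamete(parentA$maternal, parentA$paternal, n, L,
                        cfg$chromosomes, cfg$crossovers)
  gm <- cpp_mutate_genome(gm, cfg$mutation_rate, n, L)
  gp <- cpp_make_gamete(parentB$maternal, parentB$paternal, n, L,
                        cfg$chromosomes, cfg$crossovers)
  gp <- cpp_mutate_genome(gp, cfg$mutation_rate, n, L)
  new_individual(gm, gp)
}
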