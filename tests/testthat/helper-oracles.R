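# Independent brute-force evaluators used as oracles against the package's
# (partly compiled) implementation. Deliberately plain loops.

oracle_hamming <- function(a, b) {
  d <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) d <- d + 1L
  d
}

# piecewise-linear peak score by interpolation between the apex and the
# zero point at the radius
oracle_peak_score <- function(d, height, radius) {
  if (d >= radius) return(0)
  height - height * d / radius
}

oracle_strand_fitness <- function(seq, land, g) {
  f0 <- oracle_peak_score(oracle_hamming(seq, land$t0[, g]),
                          land$heights[["h0"]], land$radius0)
  f1 <- oracle_peak_score(oracle_hamming(seq, land$t1[, g]),
                          land$heights[["h1"]], land$radius1)
  max(f0, f1)
}

oracle_gene_fitness <- function(m, p, land, g, lambda) {
  fm <- oracle_strand_fitness(m, land, g)
  fp <- oracle_strand_fitness(p, land, g)
  lambda * max(fm, fp) + (1 - lambda) * min(fm, fp)
}

oracle_individual_fitness <- function(maternal, paternal, land, lambda) {
  L <- land$gene_length
  vals <- numeric(land$gene_count)
  for (g in seq_len(land$gene_count)) {
    rows <- ((g - 1) * L + 1):(g * L)
    vals[g] <- oracle_gene_fitness(maternal[rows], paternal[rows], land, g,
                                   lambda)
  }
  min(vals)
}

# every position of a gamete must come from one of the two parental strands
is_mosaic <- function(gamete, maternal, paternal) {
  all(gamete == maternal | gamete == paternal)
}

# all 4^L sequences of length L as an L-column matrix (rows = sequences)
enumerate_seqs <- function(L) {
  as.matrix(expand.grid(rep(list(0:3), L), KEEP.OUT.ATTRS = FALSE))
}

# population with 3 individuals at fitnesses 15 (peak-0 top), 10 (peak-1
# top) and 0 (outside both peaks), used for tournament-rank statistics
trio_population <- function(land) {
  pop <- initialize_population(3, land, shuffle = FALSE)
  off <- (land$t1[, 1] + 2L) %% 4L # far from both targets
  stopifnot(sum(off != land$t0[, 1]) >= land$radius0,
            sum(off != land$t1[, 1]) >= land$radius1)
  pop$maternal[, 3] <- off
  pop$paternal[, 3] <- off
  pop
}
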