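#' Construct a per-gene two-peak fitness landscape
#'
#' Builds the fitness landscape used throughout the simulator: each of `n`
#' genes of length `L` carries two peaks, a narrow high peak (peak 0, height
#' `h0`, radius `S * r0`) and a broad lower peak (peak 1, height `h1`, radius
#' `S * r1`), whose target sequences sit `S * D` mutational steps apart. The
#' peak-0 target of every gene is the all-`0` sequence; each peak-1 target is
#' drawn independently per gene by picking `S * D` positions uniformly
#' without replacement and setting each to one of the three non-zero symbols
#' uniformly.
#'
#' A peak's radius is the Hamming distance from its target at which fitness
#' reaches zero; within the radius fitness decays linearly from the apex
#' (see [peak_fitness()]). The peaks must not meet or overlap
#' (`S*D > S*(r0 + r1)`), and the inter-peak distance cannot exceed the gene
#' length.
#'
#' @param n Number of genes per individual.
#' @param L Gene length in bases. The 4-letter alphabet is `0:3`.
#' @param r0,r1 Base radii of peak 0 (narrow, high) and peak 1 (broad, low).
#' @param D Base Hamming distance between the two peak targets.
#' @param S Integer scale applied to both radii and the distance
#'   (radii become `S*r0`, `S*r1`; the distance `S*D`).
#' @param h0,h1 Peak heights (relative fitness scores); `h0 > h1` required.
#' @param seed Optional integer seed for the peak-1 target draws.
#' @return An object of class `cmr_landscape`: a list with the geometry
#'   scalars and the `L x n` integer target matrices `t0`, `t1`.
#' @examples
#' land <- make_landscape(n = 1, L = 1000, seed = 1)
#' land$distance # 10
#' @export
make_landscape <- function(n = 1L, L = 1000L, r0 = 2, r1 = 5, D = 10,
                           S = 1L, h0 = 15, h1 = 10, seed = NULL) {
  stopifnot(n >= 1, L >= 1, r0 >= 1, r1 >= 1, D >= 1, S >= 1,
            S == as.integer(S))
  if (h0 <= h1 || h1 <= 0) {
    stop("peak heights must satisfy h0 > h1 > 0 (peak 0 is the fitter peak)")
  }
  if (S * D <= S * (r0 + r1)) {
    stop("peaks meet or overlap: need S*D > S*(r0 + r1)")
  }
  if (S * D > L) {
    stop("inter-peak distance S*D exceeds the gene length L")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); L <- as.integer(L); S <- as.integer(S)
  d_eff <- as.integer(S * D)
  t0 <- matrix(0L, nrow = L, ncol = n)
  t1 <- matrix(0L, nrow = L, ncol = n)
  for (g in seq_len(n)) {
    pos <- sample.int(L, d_eff)
    t1[pos, g] <- sample(1:3, d_eff, replace = TRUE)
  }
  structure(
    list(
      gene_count = n, gene_length = L, scale = S,
      base_radii = c(r0 = r0, r1 = r1), base_distance = D,
      heights = c(h0 = h0, h1 = h1),
      radius0 = S * r0, radius1 = S * r1, distance = d_eff,
      t0 = t0, t1 = t1
    ),
    class = "cmr_landscape"
  )
}

#' @export
print.cmr_landscape <- function(x, ...) {
  cat("<cmr_landscape> ", x$gene_count, " gene(s) x ", x$gene_length,
      " bp\n", sep = "")
  cat("  peak 0: height ", x$heights[["h0"]], ", radius ", x$radius0,
      "  |  peak 1: height ", x$heights[["h1"]], ", radius ", x$radius1,
      "\n", sep = "")
  cat("  inter-peak distance ", x$distance, " (scale S = ", x$scale, ")\n",
      sep = "")
  invisible(x)
}

#' Fitness contributed by a single peak at a given Hamming distance
#'
#' Linear decay from the apex: `height` at distance 0, zero at and beyond the
#' radius (the radius is the point of zero fitness), strictly decreasing in
#' between: `height * max(0, 1 - d / radius)`.
#'
#' @param d Hamming distance(s) from the peak target (vectorised).
#' @param height Peak height.
#' @param radius Peak radius in bases.
#' @return Numeric fitness score(s).
#' @examples
#' peak_fitness(0:3, height = 15, radius = 2) # 15 7.5 0 0
#' @export
peak_fitness <- function(d, height, radius) {
  stopifnot(height > 0, radius >= 1, all(d >= 0))
  height * pmax(0, 1 - d / radius)
}

#' Fitness of one haploid sequence on a gene's two-peak landscape
#'
#' Evaluates the sequence against both peak targets of gene `gene` and keeps
#' the larger contribution. Because the peaks neither meet nor overlap, at
#' most one contribution is positive; when both are zero (the neutral space)
#' the supplying peak is reported as `NA`.
#'
#' @param seq Integer vector of length `L` over `0:3`.
#' @param landscape A [make_landscape()] object.
#' @param gene Gene index (1-based).
#' @return A list with `fitness` (numeric) and `peak` (`0`, `1`, or `NA`).
#' @export
sequence_fitness <- function(seq, landscape, gene = 1L) {
  L <- landscape$gene_length
  if (length(seq) != L) {
    stop("sequence length ", length(seq), " does not match gene length ", L)
  }
  d0 <- sum(seq != landscape$t0[, gene])
  d1 <- sum(seq != landscape$t1[, gene])
  f0 <- peak_fitness(d0, landscape$heights[["h0"]], landscape$radius0)
  f1 <- peak_fitness(d1, landscape$heights[["h1"]], landscape$radius1)
  if (f0 == 0 && f1 == 0) {
    list(fitness = 0, peak = NA_integer_)
  } else if (f0 >= f1) {
    list(fitness = f0, peak = 0L)
  } else {
    list(fitness = f1, peak = 1L)
  }
}

#' Diploid fitness of one gene
#'
#' The maternal and paternal gene segments are scored with
#' [sequence_fitness()]; writing `f_max` for the larger and `f_min` for the
#' smaller, the gene fitness is the dominance-weighted combination
#' `lambda * f_max + (1 - lambda) * f_min`. With `lambda` just below 1 the
#' fitter allele dominates but the weaker allele still contributes, so
#' neither strand can drift neutrally.
#'
#' @param maternal,paternal Integer vectors of length `L`.
#' @inheritParams sequence_fitness
#' @param lambda Dominance weight in `[0, 1]`.
#' @return Numeric fitness score.
#' @export
gene_fitness <- function(maternal, paternal, landscape, gene = 1L,
                         lambda = 0.999999999999999) {
  stopifnot(lambda >= 0, lambda <= 1)
  fm <- sequence_fitness(maternal, landscape, gene)$fitness
  fp <- sequence_fitness(paternal, landscape, gene)$fitness
  lambda * max(fm, fp) + (1 - lambda) * min(fm, fp)
}

#' Fitness of a diploid individual
#'
#' Each of the `n` genes is scored with the dominance-weighted rule of
#' [gene_fitness()]; the individual's fitness is the minimum over genes, a
#' strong-epistasis rule modelling essential genes: losing any one gene's
#' peaks cannot be masked by the others.
#'
#' @param individual A `cmr_individual` (see [new_individual()]), or a list
#'   with `maternal` and `paternal` genome-length integer vectors.
#' @param landscape A [make_landscape()] object.
#' @param lambda Dominance weight in `[0, 1]`.
#' @return Numeric fitness score.
#' @export
individual_fitness <- function(individual, landscape,
                               lambda = 0.999999999999999) {
  stopifnot(lambda >= 0, lambda <= 1)
  G <- landscape$gene_count * landscape$gene_length
  stopifnot(length(individual$maternal) == G,
            length(individual$paternal) == G)
  cpp_individual_fitness(
    as.integer(individual$maternal), as.integer(individual$paternal),
    landscape$t0, landscape$t1,
    landscape$heights[["h0"]], landscape$heights[["h1"]],
    landscape$radius0, landscape$radius1, lambda
  )
}

#' Landscape footprint arithmetic
#'
#' How much of a gene the two peaks occupy, under the convention that each
#' peak spans `2 * radius` positions of the 1-D transect and the footprint
#' adds the inter-peak distance: `peaks = (2*S*r0 + 2*S*r1) / L` and
#' `footprint = (2*S*r0 + 2*S*r1 + S*D) / L`. The neutral gap is the
#' stretch between the radii, `S*D - S*(r0 + r1)`. For the canonical
#' geometry (r0 = 2, r1 = 5, D = 10, L = 1000) this gives a 2.4% footprint
#' and 1.4% peaks-only share at S = 1, doubling at S = 2.
#'
#' @inheritParams make_landscape
#' @return A one-row tibble with `combined_radii`, `neutral_gap`,
#'   `peaks_fraction` and `footprint_fraction` (fractions of `L`).
#' @examples
#' footprint_stats(r0 = 2, r1 = 5, D = 10, S = 1, L = 1000)
#' @export
footprint_stats <- function(r0 = 2, r1 = 5, D = 10, S = 1, L = 1000) {
  stopifnot(r0 >= 0, r1 >= 0, D > 0, S >= 1, L >= 1)
  combined <- S * (r0 + r1)
  tibble::tibble(
    combined_radii = combined,
    neutral_gap = S * D - combined,
    peaks_fraction = (2 * S * r0 + 2 * S * r1) / L,
    footprint_fraction = (2 * S * r0 + 2 * S * r1 + S * D) / L
  )
}

#' Serialise a landscape to a structured text file
#'
#' Writes every scalar plus the peak targets (as strings over `0123`) so a
#' run can be reproduced exactly; [read_landscape()] inverts it.
#'
#' @param landscape A [make_landscape()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  lines <- c(
    "# cmrsim landscape v1",
    paste("gene_count", landscape$gene_count),
    paste("gene_length", landscape$gene_length),
    paste("scale", landscape$scale),
    paste("r0", landscape$base_radii[["r0"]]),
    paste("r1", landscape$base_radii[["r1"]]),
    paste("distance", landscape$base_distance),
    paste("h0", landscape$heights[["h0"]]),
    paste("h1", landscape$heights[["h1"]])
  )
  for (g in seq_len(landscape$gene_count)) {
    lines <- c(
      lines,
      paste0("t0 ", g, " ", paste(landscape$t0[, g], collapse = "")),
      paste0("t1 ", g, " ", paste(landscape$t1[, g], collapse = ""))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param path File path.
#' @return A `cmr_landscape` object.
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  kv <- list()
  targets <- list(t0 = list(), t1 = list())
  for (p in parts) {
    if (p[[1]] %in% c("t0", "t1")) {
      targets[[p[[1]]]][[as.integer(p[[2]])]] <-
        as.integer(strsplit(p[[3]], "")[[1]])
    } else {
      kv[[p[[1]]]] <- as.numeric(p[[2]])
    }
  }
  land <- make_landscape(
    n = kv$gene_count, L = kv$gene_length, r0 = kv$r0, r1 = kv$r1,
    D = kv$distance, S = kv$scale, h0 = kv$h0, h1 = kv$h1
  )
  land$t0 <- matrix(unlist(targets$t0), nrow = land$gene_length)
  land$t1 <- matrix(unlist(targets$t1), nrow = land$gene_length)
  storage.mode(land$t0) <- "integer"
  storage.mode(land$t1) <- "integer"
  land
}
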