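#' Export a population to FASTA
#'
#' Writes `2 N` records, one per strand, with the 4-letter alphabet mapped
#' `0 -> A`, `1 -> C`, `2 -> G`, `3 -> T` and record IDs encoding the
#' individual and strand (`ind0007/maternal`); [import_population()]
#' inverts the mapping losslessly.
#'
#' @param pop A `cmr_population`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_population <- function(pop, path) {
  N <- population_size(pop)
  to_str <- function(m) {
    chartr("0123", "ACGT", apply(m, 2, paste, collapse = ""))
  }
  seqs <- c(to_str(pop$maternal), to_str(pop$paternal))
  ids <- c(sprintf("ind%04d/maternal", seq_len(N)),
           sprintf("ind%04d/paternal", seq_len(N)))
  ord <- order(rep(seq_len(N), 2), rep(1:2, each = N)) # interleave strands
  x <- Biostrings::DNAStringSet(seqs[ord])
  names(x) <- ids[ord]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Import a population written by [export_population()]
#'
#' @param path FASTA file path.
#' @param landscape The `cmr_landscape` the population evolves on.
#' @return A `cmr_population`.
#' @export
import_population <- function(path, landscape) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- names(x)
  m <- regmatches(ids, regexec("^ind([0-9]+)/(maternal|paternal)$", ids))
  if (any(lengths(m) != 3)) {
    stop("unrecognised record ID(s); expected ind<index>/<strand>")
  }
  idx <- vapply(m, function(p) as.integer(p[2]), integer(1))
  strand <- vapply(m, function(p) p[3], character(1))
  N <- max(idx)
  G <- unique(Biostrings::width(x))
  stopifnot(length(G) == 1,
            G == landscape$gene_count * landscape$gene_length)
  to_int <- function(s) {
    as.integer(strsplit(chartr("ACGT", "0123", as.character(s)), "")[[1]])
  }
  mat <- matrix(0L, nrow = G, ncol = N)
  pat <- matrix(0L, nrow = G, ncol = N)
  for (j in seq_along(x)) {
    v <- to_int(x[j])
    if (strand[j] == "maternal") mat[, idx[j]] <- v else pat[, idx[j]] <- v
  }
  structure(list(maternal = mat, paternal = pat, landscape = landscape),
            class = "cmr_population")
}
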