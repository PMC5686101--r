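# embedded checksums guard the bundled reference tables against silent edits
.fixture_md5 <- c(
  allele_distances = "5acf13d2ce462369a3b1902800972c9b",
  bio_rates = "394f98eef41f7da4f552a855d9757630",
  crossover_rates = "f0de4275953a8005ff092140ca30cb1f",
  reference_cmrs = "a1c96dfd7c39f37f01953d106f38c430"
)

#' Load a bundled reference table
#'
#' Static reference data shipped with the package, for plots and reports
#' only (they never feed the simulator):
#' * `"bio_rates"` — published mutation-rate estimates for eukaryotic
#'   species (per base or per genome; per generation, cell division or
#'   genome-year).
#' * `"allele_distances"` — published genetic distances between alleles of
#'   individual genes (percent difference, amino acids, SNPs, base pairs).
#' * `"crossover_rates"` — female/male crossover counts per cell and per
#'   chromosome bivalent in *Arabidopsis thaliana*.
#' * `"reference_cmrs"` — published full-protocol CMR values (20 x 100
#'   runs, 10,000 generations) for opt-in comparison against long runs.
#'
#' Files are validated at load time against embedded MD5 checksums.
#'
#' @param name One of the fixture names above.
#' @return A tibble.
#' @examples
#' load_fixture("bio_rates")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% names(.fixture_md5)) {
    stop("unknown fixture ", deparse(name), "; available: ",
         paste(names(.fixture_md5), collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "cmrsim",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]]))) {
    stop("fixture ", name, " failed its checksum (", sum,
         "); the bundled file has been altered")
  }
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
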