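# Packaged in-repo fixtures: the 23-genome TI-PKS census, the two-topology
# log-likelihood table for the atranorin (PKS23) tree comparison, and a
# synthetic stand-in for the PKS23 reference protein.

#' Packaged 23-genome biosynthetic gene cluster census
#'
#' Per-genome counts of predicted biosynthetic gene clusters and TI-PKS
#' families for twenty-three lichen-forming fungal genomes: total clusters,
#' Type I PKS total and its non-reducing (`nr`), reducing (`r`) and
#' partially reducing (`pr`) breakdown, hybrid PKS-NRPS, and NRPS counts
#' (confident and putative).
#'
#' @return Tibble with 23 rows (class `census_table`).
#' @examples
#' census_fixture()
#' @export
census_fixture <- function() {
  path <- system.file("extdata", "ti_pks_census.tsv", package = "lichenpks",
                      mustWork = TRUE)
  out <- readr::read_tsv(path, col_types = "cciiiiiiii")
  class(out) <- c("census_table", class(out))
  out
}

#' Packaged two-topology log-likelihood fixture
#'
#' Total log-likelihoods (and the published test statistics, for reference)
#' of the two competing placements of the *Bacidia* PKS23 gene: topology 1
#' groups *Bacidia* with Cladoniaceae, topology 2 groups Cladoniaceae with
#' Parmeliaceae and leaves *Bacidia* sister to that pair.
#'
#' @return Tibble with columns `tree`, `logl`, `p_kh`, `p_sh`, `c_elw`,
#'   `p_au`.
#' @export
toptest_fixture <- function() {
  tibble(
    tree = c("Bacidia+Cladoniaceae", "Cladoniaceae+Parmeliaceae"),
    logl = c(-28054.52811, -28108.54142),
    p_kh = c(0.495, 0.0126),
    p_sh = c(0.814, 0.0126),
    c_elw = c(0.496, 0.00853),
    p_au = c(0.566, 0.0081)
  )
}

#' Synthetic PKS23 reference protein
#'
#' A deterministic synthetic stand-in for an atranorin-cluster core PKS
#' protein, used as the query of the atranorin screen on synthetic genomes
#' (the screen itself is agnostic to the reference supplied). The packaged
#' sequence is random, not a real PKS23; real analyses should pass a real
#' reference protein.
#'
#' @return Single named character string (amino-acid sequence).
#' @export
pks23_reference <- function() {
  path <- system.file("extdata", "synthetic_pks23_reference.faa",
                      package = "lichenpks", mustWork = TRUE)
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), sub(" .*", "", names(seqs)))
}
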