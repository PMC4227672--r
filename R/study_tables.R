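#' Published read-accounting table for the H. halys transcriptome study
#'
#' Per-sample raw and cleaned read and base counts for the four sequenced
#' developmental stages of *Halyomorpha halys* (SE100, Illumina HiSeq
#' 1000), as printed in the study's quality-control accounting table.
#' Useful for checking the retention arithmetic ([qc_total()]) and as the
#' per-sample cleaned totals that normalize digital expression counts.
#'
#' @return Tibble with columns `sample`, `raw_reads`, `raw_bases`,
#'   `cleaned_reads`, `cleaned_bases` and one row per stage
#'   (`nymph2`, `nymph4`, `adult_male`, `adult_female`).
#' @examples
#' qc_total(hhalys_read_accounting())
#' @export
hhalys_read_accounting <- function() {
  tibble::tribble(
    ~sample,        ~raw_reads,  ~raw_bases,     ~cleaned_reads, ~cleaned_bases,
    "nymph2",       196439408,   19643940800,    113365193,      11304674285,
    "nymph4",       208313504,   20831350400,    105109728,      10477330878,
    "adult_male",   189721966,   18972196600,    113154644,      11288454095,
    "adult_female", 164646253,   16464625300,    107985660,      10774361340
  )
}

#' Published annotation-mapping counts per homology tier
#'
#' Distinct NR protein counts per tier and how many of them mapped to
#' annotated UniProtKB entries in the study, with the unique Pfam and
#' Molecular Function GO term counts extracted from the mapped set.
#'
#' @return Tibble with columns `tier`, `distinct_nr`, `mapped_nr`,
#'   `unique_pfam`, `unique_go_mf`.
#' @examples
#' dplyr::mutate(hhalys_annotation_counts(),
#'               mapped_pct = round(100 * mapped_nr / distinct_nr))
#' @export
hhalys_annotation_counts <- function() {
  tibble::tribble(
    ~tier,    ~distinct_nr, ~mapped_nr, ~unique_pfam, ~unique_go_mf,
    "gold",   2580,         1785,       1273,         459,
    "silver", 6527,         4193,       1941,         640
  )
}
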