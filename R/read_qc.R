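#' Parameters for read cleaning
#'
#' Defaults reproduce the study's cleaning procedure for SE100 HiSeq
#' reads: terminal bases with Phred < 21 are clipped (forcing read ends
#' below a 1% error rate), trimmed reads shorter than 36 bases are purged,
#' as are reads in which 10% or more of bases have Phred <= 20; surviving
#' bases with Phred < 21 are masked with `N`.
#'
#' @param trim_threshold Phred score below which terminal bases are
#'   clipped (strict `<`; default 21).
#' @param min_length Minimum trimmed read length retained (default 36).
#' @param bad_base_threshold Phred score at or below which a base counts
#'   as bad for the fraction filter (inclusive `<=`; default 20).
#' @param bad_fraction Reads with at least this fraction of bad bases are
#'   purged (inclusive `>=`; default 0.10).
#' @param mask_threshold Phred score below which surviving bases are
#'   masked (strict `<`; default 21).
#' @param mask_symbol Masking symbol (default `"N"`).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(trim_threshold = 21, min_length = 36,
                      bad_base_threshold = 20, bad_fraction = 0.10,
                      mask_threshold = 21, mask_symbol = "N") {
  stopifnot(trim_threshold >= 0, min_length >= 0, bad_base_threshold >= 0,
            bad_fraction > 0, bad_fraction <= 1, mask_threshold >= 0,
            nchar(mask_symbol) == 1L)
  structure(
    list(trim_threshold = trim_threshold, min_length = min_length,
         bad_base_threshold = bad_base_threshold,
         bad_fraction = bad_fraction, mask_threshold = mask_threshold,
         mask_symbol = mask_symbol),
    class = "qc_params"
  )
}

# Per-read retained index range after terminal clipping: first and last
# position with quality >= threshold. Returns 2-column matrix (start, end);
# start > end encodes a fully clipped read.
trim_range <- function(qualities, threshold) {
  t(vapply(qualities, function(q) {
    keep <- which(q >= threshold)
    if (length(keep) == 0L) c(1L, 0L) else range(keep)
  }, integer(2)))
}

#' Clip low-quality terminal spans from reads
#'
#' Removes the maximal prefix and maximal suffix in which every base has
#' quality below `threshold`; interior bases are untouched. A read whose
#' bases are all below threshold becomes empty.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `qualities`).
#' @param threshold Phred threshold (strict `<`; default 21).
#' @return Read tibble of the same rows, trimmed.
#' @export
trim_terminal <- function(reads, threshold = 21) {
  if (nrow(reads) == 0L) return(reads)
  rng <- trim_range(reads$qualities, threshold)
  reads$sequence <- substr(reads$sequence, rng[, 1L], rng[, 2L])
  reads$qualities <- purrr::map2(reads$qualities, seq_len(nrow(reads)),
                                 function(q, i) {
    if (rng[i, 1L] > rng[i, 2L]) integer(0) else q[rng[i, 1L]:rng[i, 2L]]
  })
  reads
}

#' Length and bad-base-fraction read filter
#'
#' Evaluated on trimmed reads: a read passes iff its length is at least
#' `min_length` and strictly less than `bad_fraction` of its bases have
#' quality at or below `bad_base_threshold`. Empty reads fail (never
#' error).
#'
#' @param reads Read tibble (already trimmed).
#' @param params `qc_params()` list (or arguments overriding its fields).
#' @return Logical vector, one entry per read.
#' @export
passes_filters <- function(reads, params = qc_params()) {
  if (nrow(reads) == 0L) return(logical(0))
  len <- nchar(reads$sequence)
  n_bad <- vapply(reads$qualities,
                  function(q) sum(q <= params$bad_base_threshold),
                  integer(1))
  frac_bad <- ifelse(len > 0L, n_bad / len, 1)
  len >= params$min_length & frac_bad < params$bad_fraction
}

#' Mask low-quality bases
#'
#' Replaces every base with quality below `threshold` by `symbol`. The
#' recorded quality scores are retained (masking is reversible evidence,
#' not erasure), so base counts and read lengths never change.
#'
#' @param reads Read tibble.
#' @param threshold Phred threshold (strict `<`; default 21).
#' @param symbol Replacement character (default `"N"`).
#' @return Read tibble with masked sequences.
#' @export
mask_low_quality <- function(reads, threshold = 21, symbol = "N") {
  if (nrow(reads) == 0L) return(reads)
  reads$sequence <- purrr::map2_chr(reads$sequence, reads$qualities,
                                    function(s, q) {
    low <- which(q < threshold)
    if (length(low) == 0L) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars[low] <- symbol
    paste(chars, collapse = "")
  })
  reads
}

#' Clean one sample's reads and account for retention
#'
#' Applies the full cleaning pipeline in order: terminal clipping, then
#' the length / bad-fraction filter, then masking. Returns the surviving
#' reads together with a retention report in the study's accounting
#' layout (raw and cleaned read and base counts with percentages).
#' Cleaned bases are counted after trimming; masking does not change base
#' counts.
#'
#' @param reads Read tibble for one sample.
#' @param params `qc_params()`.
#' @param sample Sample label recorded in the report.
#' @return List with `reads` (cleaned tibble) and `report` (one-row
#'   tibble: `sample`, `raw_reads`, `raw_bases`, `cleaned_reads`,
#'   `cleaned_bases`, `reads_retained_pct`, `bases_retained_pct`).
#' @export
clean_sample <- function(reads, params = qc_params(), sample = "sample") {
  raw_reads <- nrow(reads)
  raw_bases <- sum(nchar(reads$sequence))
  trimmed <- trim_terminal(reads, params$trim_threshold)
  kept <- trimmed[passes_filters(trimmed, params), ]
  cleaned <- mask_low_quality(kept, params$mask_threshold,
                              params$mask_symbol)
  report <- qc_report(
    sample = sample, raw_reads = raw_reads, raw_bases = raw_bases,
    cleaned_reads = nrow(cleaned),
    cleaned_bases = sum(nchar(cleaned$sequence))
  )
  list(reads = cleaned, report = report)
}

#' Build a retention report row from raw / cleaned tallies
#'
#' Percentages are `100 * cleaned / raw`, defined as 0 for an empty
#' sample. This is also the arithmetic behind the study-scale accounting
#' table bundled as [hhalys_read_accounting].
#'
#' @param sample Sample label.
#' @param raw_reads,raw_bases,cleaned_reads,cleaned_bases Counts.
#' @return One-row tibble.
#' @export
qc_report <- function(sample, raw_reads, raw_bases, cleaned_reads,
                      cleaned_bases) {
  stopifnot(all(cleaned_reads <= raw_reads),
            all(cleaned_bases <= raw_bases))
  tibble::tibble(
    sample = sample,
    raw_reads = raw_reads, raw_bases = raw_bases,
    cleaned_reads = cleaned_reads, cleaned_bases = cleaned_bases,
    reads_retained_pct = ifelse(raw_reads > 0,
                                100 * cleaned_reads / raw_reads, 0),
    bases_retained_pct = ifelse(raw_bases > 0,
                                100 * cleaned_bases / raw_bases, 0)
  )
}

#' Global retention across per-sample reports
#'
#' Sums the per-sample raw and cleaned tallies and recomputes retention
#' percentages on the totals (count-weighted, not an average of per-sample
#' percentages).
#'
#' @param reports Tibble of per-sample report rows ([qc_report()] layout).
#' @param label Label for the total row (default `"total"`).
#' @return One-row tibble in the same layout.
#' @export
qc_total <- function(reports, label = "total") {
  qc_report(
    sample = label,
    raw_reads = sum(reports$raw_reads),
    raw_bases = sum(reports$raw_bases),
    cleaned_reads = sum(reports$cleaned_reads),
    cleaned_bases = sum(reports$cleaned_bases)
  )
}
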