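#' Parameters for digital expression counting
#'
#' A read increments a PUT's digital expression level only if not less
#' than 95% of the read's length aligned with 100% sequence identity.
#' Identity is enforced over the aligned span (zero mismatches and every
#' aligned base a match); the 95% rule governs how much of the read must
#' be covered.
#'
#' @param min_aligned_frac Minimum aligned fraction of the read length
#'   (inclusive; default 0.95).
#' @param required_identity Required identity over the aligned span
#'   (default 1.0; lowering it admits `mismatches / aligned_len` up to
#'   `1 - required_identity`).
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(min_aligned_frac = 0.95, required_identity = 1.0) {
  stopifnot(min_aligned_frac > 0, min_aligned_frac <= 1,
            required_identity > 0, required_identity <= 1)
  structure(list(min_aligned_frac = min_aligned_frac,
                 required_identity = required_identity),
            class = "quant_params")
}

#' Filter alignments to those that may increment a count
#'
#' @param alignments Alignment tibble ([read_psl()] layout).
#' @param params `quant_params()`.
#' @return The qualifying subset, same columns.
#' @export
qualifying_alignments <- function(alignments, params = quant_params()) {
  min_matches <- ceiling(params$required_identity * alignments$aligned_len)
  keep <- alignments$aligned_len >=
    params$min_aligned_frac * alignments$read_len &
    alignments$matches >= min_matches &
    alignments$mismatches <= alignments$aligned_len - min_matches
  alignments[keep, ]
}

#' Assign each read to at most one PUT
#'
#' Among a read's qualifying alignments only the highest-scoring one is
#' considered; score ties are resolved by the lexicographically smallest
#' `put_id`, a deterministic stand-in for the study's "arbitrary"
#' representative, so output is identical across runs and input
#' orderings.
#'
#' @param qualifying Qualifying alignment tibble.
#' @return Tibble with `read_id` and `put_id`, one row per assigned read.
#' @export
assign_reads <- function(qualifying) {
  qualifying |>
    dplyr::arrange(.data$read_id, dplyr::desc(.data$score), .data$put_id) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE) |>
    dplyr::select("read_id", "put_id")
}

#' Aggregate read assignments to protein-coding genes and normalize
#'
#' PUT-level counts of all PUTs corresponding to the same NR protein
#' (gene duplication, alternative splicing) are summed and attributed to
#' that gene; normalized abundance is the gene's absolute digital count
#' divided by the sample's total number of unassembled, cleaned reads.
#' Genes with zero assigned reads are materialized with `normalized = 0`
#' so "absent" stays distinct from "unmeasured".
#'
#' @param read_assignments [assign_reads()] output.
#' @param put_to_gene Tibble with `put_id` and `gene_id` (typically the
#'   gold-tier best-hit subjects from [classify_tiers()]).
#' @param total_reads Total cleaned reads in the sample (> 0).
#' @param sample Sample label.
#' @return Tibble with `gene_id`, `sample`, `count`, `total_reads`,
#'   `normalized`, one row per gene in `put_to_gene`.
#' @export
aggregate_to_genes <- function(read_assignments, put_to_gene, total_reads,
                               sample) {
  if (total_reads <= 0) {
    stop("total_reads must be positive", call. = FALSE)
  }
  unknown <- setdiff(read_assignments$put_id, put_to_gene$put_id)
  if (length(unknown) > 0L) {
    stop("read assigned to put_id with no gene mapping: ", unknown[1L],
         call. = FALSE)
  }
  read_assignments |>
    dplyr::left_join(put_to_gene, by = "put_id") |>
    dplyr::count(.data$gene_id, name = "count") |>
    dplyr::right_join(dplyr::distinct(put_to_gene["gene_id"]),
                      by = "gene_id") |>
    dplyr::mutate(
      sample = sample,
      count = dplyr::coalesce(.data$count, 0L),
      total_reads = total_reads,
      normalized = .data$count / total_reads
    ) |>
    dplyr::arrange(.data$gene_id) |>
    dplyr::select("gene_id", "sample", "count", "total_reads",
                  "normalized")
}

#' Quantify one sample end to end
#'
#' Convenience wrapper: filter alignments, assign reads, aggregate to
#' genes. The gene map is taken from the gold-tier rows of a
#' [classify_tiers()] result.
#'
#' @param alignments [read_psl()] tibble of cleaned reads vs trimmed
#'   gold PUTs.
#' @param assignments [classify_tiers()] output.
#' @param total_reads Total cleaned reads in the sample.
#' @param sample Sample label.
#' @param params `quant_params()`.
#' @return [aggregate_to_genes()] tibble.
#' @export
quantify_sample <- function(alignments, assignments, total_reads, sample,
                            params = quant_params()) {
  gold <- dplyr::filter(assignments, .data$tier == "gold")
  put_to_gene <- dplyr::select(gold, "put_id", gene_id = "subject_id")
  qual <- qualifying_alignments(alignments, params)
  qual <- qual[qual$put_id %in% put_to_gene$put_id, ]
  aggregate_to_genes(assign_reads(qual), put_to_gene, total_reads, sample)
}
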