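#' Parameters for three-tier homology triage
#'
#' Defaults are the study's criteria. Gold: single-HSP hit, query at
#' least 300 nt, subject protein at least 100 residues, at least 75% of
#' aligned residues positively similar, and alignment covering at least
#' 90% of the subject's length. Silver: query at least 100 nt and subject
#' coverage at least 75%. Bronze: query at least 100 nt and coverage at
#' least 30%. All comparisons are inclusive ("at least").
#'
#' @param gold_min_query_len,gold_min_subject_len,gold_min_positive_frac,gold_min_coverage,gold_max_hsps
#'   Gold-tier thresholds (300 nt, 100 aa, 0.75, 0.90, 1).
#' @param lower_min_query_len Minimum query length for silver and bronze
#'   (100 nt).
#' @param silver_min_coverage,bronze_min_coverage Subject-coverage floors
#'   (0.75, 0.30).
#' @param coverage_mode `"align_len"` (default) uses the best HSP's
#'   alignment length as the coverage numerator; `"subject_span"` is not
#'   computable from this dialect's columns and reserved for richer
#'   inputs.
#' @return A list of class `tier_params`.
#' @export
tier_params <- function(gold_min_query_len = 300, gold_min_subject_len = 100,
                        gold_min_positive_frac = 0.75,
                        gold_min_coverage = 0.90, gold_max_hsps = 1,
                        lower_min_query_len = 100,
                        silver_min_coverage = 0.75,
                        bronze_min_coverage = 0.30,
                        coverage_mode = c("align_len", "subject_span")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(bronze_min_coverage < silver_min_coverage,
            silver_min_coverage < gold_min_coverage,
            gold_min_coverage <= 1)
  structure(
    list(gold_min_query_len = gold_min_query_len,
         gold_min_subject_len = gold_min_subject_len,
         gold_min_positive_frac = gold_min_positive_frac,
         gold_min_coverage = gold_min_coverage,
         gold_max_hsps = gold_max_hsps,
         lower_min_query_len = lower_min_query_len,
         silver_min_coverage = silver_min_coverage,
         bronze_min_coverage = bronze_min_coverage,
         coverage_mode = coverage_mode),
    class = "tier_params"
  )
}

tier_levels <- c("gold", "silver", "bronze", "unclassified")

#' Select each query's best hit
#'
#' Only the top-scoring hit per PUT is considered for tiering: maximal
#' bit score, ties broken by lower E-value, then by lexicographically
#' smallest subject identifier so the choice is deterministic and
#' order-free.
#'
#' @param hits Hit tibble ([read_blast_tab()] layout), any number of
#'   queries.
#' @param max_evalue Optional E-value ceiling applied before selection
#'   (default `Inf`: the study imposed none).
#' @return Tibble with one row per `put_id`.
#' @export
best_hits <- function(hits, max_evalue = Inf) {
  hits |>
    dplyr::filter(.data$e_value <= max_evalue) |>
    dplyr::arrange(.data$put_id, dplyr::desc(.data$bit_score),
                   .data$e_value, .data$subject_id) |>
    dplyr::distinct(.data$put_id, .keep_all = TRUE)
}

#' Partition PUTs into gold / silver / bronze tiers
#'
#' Applies the tier criteria to each PUT's best hit. Tiers are evaluated
#' in order of decreasing stringency, so every PUT receives exactly one
#' label; PUTs without a hit, or failing all three tiers, are
#' `unclassified`.
#'
#' @param puts PUT tibble ([read_puts()] layout).
#' @param hits Hit tibble; reduced internally via [best_hits()].
#' @param params `tier_params()`.
#' @param max_evalue Optional E-value ceiling forwarded to [best_hits()].
#' @return Tibble with one row per PUT: `put_id`, `tier` (factor
#'   gold/silver/bronze/unclassified), `subject_id`, `query_len`,
#'   `subject_len`, `hsp_count`, `positive_frac`, `coverage`, plus the
#'   best hit's coordinates (`q_start`, `q_end`, `query_frame`) needed by
#'   [trim_translate()].
#' @export
classify_tiers <- function(puts, hits, params = tier_params(),
                           max_evalue = Inf) {
  if (anyDuplicated(puts$put_id)) {
    stop("duplicate put_id among PUTs: ",
         puts$put_id[duplicated(puts$put_id)][1L], call. = FALSE)
  }
  unknown <- setdiff(hits$put_id, puts$put_id)
  if (length(unknown) > 0L) {
    stop("hits reference unknown put_id: ", unknown[1L], call. = FALSE)
  }
  best <- best_hits(hits, max_evalue)
  joined <- dplyr::left_join(
    dplyr::select(puts, "put_id", put_len = "length"),
    best, by = "put_id"
  )
  if (any(!is.na(joined$query_len) & joined$query_len != joined$put_len)) {
    bad <- joined$put_id[which(joined$query_len != joined$put_len)][1L]
    stop("query_len in hits disagrees with PUT length for '", bad, "'",
         call. = FALSE)
  }
  joined |>
    dplyr::mutate(
      query_len = .data$put_len,
      positive_frac = .data$positives / .data$align_len,
      coverage = .data$align_len / .data$subject_len,
      has_hit = !is.na(.data$subject_id),
      gold = .data$has_hit &
        .data$hsp_count <= params$gold_max_hsps &
        .data$query_len >= params$gold_min_query_len &
        .data$subject_len >= params$gold_min_subject_len &
        .data$positive_frac >= params$gold_min_positive_frac &
        .data$coverage >= params$gold_min_coverage,
      silver = !.data$gold & .data$has_hit &
        .data$query_len >= params$lower_min_query_len &
        .data$coverage >= params$silver_min_coverage,
      bronze = !.data$gold & !.data$silver & .data$has_hit &
        .data$query_len >= params$lower_min_query_len &
        .data$coverage >= params$bronze_min_coverage,
      tier = factor(
        dplyr::case_when(.data$gold ~ "gold", .data$silver ~ "silver",
                         .data$bronze ~ "bronze", TRUE ~ "unclassified"),
        levels = tier_levels
      )
    ) |>
    dplyr::select("put_id", "tier", "subject_id", "subject_desc",
                  "query_len", "subject_len", "hsp_count",
                  "positive_frac", "coverage", "q_start", "q_end",
                  "query_frame")
}

#' Count PUTs per tier
#'
#' @param assignments Output of [classify_tiers()], one row per PUT.
#' @return Tibble with `tier` and `n`; all four levels always present,
#'   counts summing to the number of PUTs.
#' @export
tier_summary <- function(assignments) {
  if (anyDuplicated(assignments$put_id)) {
    stop("duplicate put_id among tier assignments: ",
         assignments$put_id[duplicated(assignments$put_id)][1L],
         call. = FALSE)
  }
  assignments |>
    dplyr::mutate(tier = factor(.data$tier, levels = tier_levels)) |>
    dplyr::count(.data$tier, .drop = FALSE, name = "n")
}

#' Clip gold PUTs to their aligned span and translate
#'
#' End sequences not incorporated into the homology alignment are
#' clipped: the coding sequence is the query span of the best HSP
#' (`q_start..q_end`), reverse-complemented when the hit frame is
#' negative, and translated in frame 1 of the clipped sequence with the
#' standard genetic code. Codons containing `N` become `X`; a trailing
#' incomplete codon is dropped; stop codons are retained as `*` (internal
#' stops trigger a warning, not an error — chimeric assemblies make them
#' expected).
#'
#' @param puts PUT tibble with sequences.
#' @param assignments [classify_tiers()] output; only `tier == "gold"`
#'   rows are translated.
#' @return Tibble with `put_id`, `subject_id`, `trimmed_cds`, `protein`,
#'   `frame`.
#' @export
trim_translate <- function(puts, assignments) {
  gold <- dplyr::filter(assignments, .data$tier == "gold")
  gold <- dplyr::inner_join(gold,
                            dplyr::select(puts, "put_id", "sequence"),
                            by = "put_id")
  if (nrow(gold) == 0L) {
    return(tibble::tibble(put_id = character(), subject_id = character(),
                          trimmed_cds = character(), protein = character(),
                          frame = integer()))
  }
  if (any(gold$q_end > nchar(gold$sequence))) {
    bad <- gold$put_id[gold$q_end > nchar(gold$sequence)][1L]
    stop("hit coordinates for '", bad, "' extend past the PUT sequence",
         call. = FALSE)
  }
  cds <- substr(gold$sequence, gold$q_start, gold$q_end)
  neg <- gold$query_frame < 0L
  if (any(neg)) {
    cds[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(cds[neg]))
    )
  }
  trimmed_len <- (nchar(cds) %/% 3L) * 3L
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(cds, 1L, trimmed_len)),
    if.fuzzy.codon = "X"
  ))
  internal_stop <- grepl("\\*.", protein)
  if (any(internal_stop)) {
    warning(sum(internal_stop), " gold translation(s) contain internal ",
            "stop codons (e.g. '", gold$put_id[internal_stop][1L], "')",
            call. = FALSE)
  }
  tibble::tibble(
    put_id = gold$put_id, subject_id = gold$subject_id,
    trimmed_cds = cds, protein = protein, frame = gold$query_frame
  )
}
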