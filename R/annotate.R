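#' Distinct NR subjects represented in a tier
#'
#' @param assignments [classify_tiers()] output.
#' @param tier Tier label (`"gold"`, `"silver"`, `"bronze"`).
#' @return Character vector of unique subject identifiers, sorted.
#' @export
distinct_subjects <- function(assignments, tier = "gold") {
  tier <- match.arg(tier, tier_levels[1:3])
  sort(unique(
    assignments$subject_id[as.character(assignments$tier) == tier]
  ))
}

#' Transfer annotation terms from an offline mapping table onto one tier
#'
#' Mirrors the UniProt ID-mapping step performed offline: each distinct
#' NR subject of the tier is looked up in the mapping table; subjects
#' with a UniProt accession contribute their GO (Molecular Function
#' aspect), Pfam and KEGG terms. Subjects absent from the table or
#' lacking an accession are counted unmapped (logged once, never an
#' error). Statistics are per-subject, so duplicating PUTs that hit the
#' same protein changes nothing.
#'
#' @param assignments [classify_tiers()] output.
#' @param mapping Mapping tibble ([read_mapping_table()] layout).
#' @param tier Tier label (default `"gold"`).
#' @return Tibble of class `annotation_transfer`: one row per (subject,
#'   term type, term) with columns `subject_id`, `uniprot_acc`, `type`
#'   (`go_mf` / `go_other` / `pfam` / `kegg`), `term`. The
#'   [annotation_summary()] row is attached as attribute `"summary"`.
#' @export
transfer_terms <- function(assignments, mapping, tier = "gold") {
  subjects <- distinct_subjects(assignments, tier)
  map_sub <- mapping[match(subjects, mapping$nr_id), ]
  mapped <- !is.na(map_sub$uniprot_acc)
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L) {
    message(n_unmapped, " of ", length(subjects), " distinct ", tier,
            "-tier subjects have no UniProt mapping")
  }
  mm <- map_sub[mapped, ]
  mm$subject_id <- subjects[mapped]
  terms <- tidyr::pivot_longer(
    dplyr::select(mm, "subject_id", "uniprot_acc", "go_mf", "go_other",
                  "pfam", "kegg"),
    cols = c("go_mf", "go_other", "pfam", "kegg"),
    names_to = "type", values_to = "term"
  ) |>
    tidyr::unnest_longer("term") |>
    dplyr::filter(!is.na(.data$term))
  summary <- tibble::tibble(
    tier = tier,
    distinct_nr = length(subjects),
    mapped_nr = sum(mapped),
    mapped_pct = mapped_pct(sum(mapped), length(subjects)),
    unique_pfam = dplyr::n_distinct(terms$term[terms$type == "pfam"]),
    unique_go_mf = dplyr::n_distinct(terms$term[terms$type == "go_mf"])
  )
  structure(terms, summary = summary, class = c("annotation_transfer",
                                                class(terms)))
}

#' Summary row of an annotation transfer
#'
#' @param terms [transfer_terms()] result.
#' @return One-row tibble: `tier`, `distinct_nr`, `mapped_nr`,
#'   `mapped_pct`, `unique_pfam`, `unique_go_mf`.
#' @export
annotation_summary <- function(terms) {
  attr(terms, "summary")
}

#' Rounded mapping percentage
#'
#' `round(100 * mapped / distinct)`, the convention in which the study
#' reports 1,785 of 2,580 gold subjects as 69%.
#'
#' @param mapped,distinct Counts.
#' @return Integer percentage (0 when `distinct` is 0).
#' @export
mapped_pct <- function(mapped, distinct) {
  ifelse(distinct > 0, round(100 * mapped / distinct), 0)
}

#' Ranked relative term frequencies
#'
#' Occurrence counts per term over mapped subjects, divided by the total
#' number of occurrences of that term type (so frequencies over all terms
#' sum to 1), sorted descending with alphabetical tie-break, truncated to
#' `top_n` — the "ten most frequently encountered" summaries of the
#' study's annotation figures.
#'
#' @param terms [transfer_terms()] result (or any tibble with `type` and
#'   `term`).
#' @param type Term type to summarise (`"pfam"`, `"go_mf"`, `"go_other"`,
#'   `"kegg"`).
#' @param top_n Number of terms to keep (default 10; `Inf` keeps all).
#' @return Tibble with `term`, `n`, `rel_freq`.
#' @export
term_frequency <- function(terms, type = "pfam", top_n = 10) {
  if (top_n <= 0) stop("top_n must be positive", call. = FALSE)
  type <- match.arg(type, c("pfam", "go_mf", "go_other", "kegg"))
  sub <- dplyr::filter(tibble::as_tibble(terms), .data$type == !!type)
  if (nrow(sub) == 0L) {
    stop("no terms of type '", type, "' to summarise", call. = FALSE)
  }
  freq <- sub |>
    dplyr::count(.data$term, name = "n") |>
    dplyr::mutate(rel_freq = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$term)
  utils::head(freq, n = if (is.finite(top_n)) top_n else nrow(freq))
}
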