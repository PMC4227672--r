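#' Pool per-sample expression tables
#'
#' Pooled counts and totals are sums; normalized abundance is recomputed
#' from the pooled values (count-weighted, never an average of
#' proportions). Used to build the nymph (2nd + 4th instar) and adult
#' (female + male) representations.
#'
#' @param ... Two or more [aggregate_to_genes()] tibbles sharing one gene
#'   universe, or a single list of them.
#' @param sample Label for the pooled pseudo-sample.
#' @return Expression tibble in the same layout.
#' @export
pool_samples <- function(..., sample = "pooled") {
  tables <- list(...)
  if (length(tables) == 1L && !is.data.frame(tables[[1L]])) {
    tables <- tables[[1L]]
  }
  stopifnot(length(tables) >= 1L)
  universe <- sort(tables[[1L]]$gene_id)
  for (t in tables[-1L]) {
    if (!setequal(t$gene_id, universe)) {
      miss <- union(setdiff(universe, t$gene_id),
                    setdiff(t$gene_id, universe))
      stop("gene universes differ across pooled samples; mismatched: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
  }
  pooled_total <- sum(vapply(tables, function(t) t$total_reads[1L],
                             numeric(1)))
  dplyr::bind_rows(tables) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(sample = sample,
                  total_reads = pooled_total,
                  normalized = .data$count / .data$total_reads) |>
    dplyr::arrange(.data$gene_id) |>
    dplyr::select("gene_id", "sample", "count", "total_reads",
                  "normalized")
}

#' Pairwise fold-difference comparison of two expression tables
#'
#' Per gene, the fold difference places the greater normalized abundance
#' in the numerator, so it is at least 1 whenever the gene is detected on
#' both sides. A gene detected on exactly one side is `exclusive`, with
#' the study's `0.00` sentinel as its fold; a gene absent from both
#' sides is `flat` with fold 1. Direction is `up` when side `b` (the
#' later stage / female / adult side in the study's layout) is the larger.
#'
#' @param a,b Expression tibbles sharing a gene universe (`a` is the
#'   baseline column of the output).
#' @param name Comparison label (e.g. `"n4_vs_n2"`).
#' @return Tibble with `gene_id`, `comparison`, `abund_a`, `abund_b`,
#'   `fold_diff`, `direction` (`up`/`down`/`flat`), `exclusive`.
#' @export
compare_expression <- function(a, b, name) {
  if (!setequal(a$gene_id, b$gene_id)) {
    miss <- union(setdiff(a$gene_id, b$gene_id),
                  setdiff(b$gene_id, a$gene_id))
    stop("gene universes differ between sides; mismatched: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(
    dplyr::select(a, "gene_id", abund_a = "normalized"),
    dplyr::select(b, "gene_id", abund_b = "normalized"),
    by = "gene_id"
  ) |>
    dplyr::mutate(
      comparison = name,
      exclusive = xor(.data$abund_a == 0, .data$abund_b == 0),
      fold_diff = dplyr::case_when(
        .data$exclusive ~ 0,
        .data$abund_a == 0 & .data$abund_b == 0 ~ 1,
        TRUE ~ pmax(.data$abund_a, .data$abund_b) /
          pmin(.data$abund_a, .data$abund_b)
      ),
      direction = dplyr::case_when(
        .data$abund_b > .data$abund_a ~ "up",
        .data$abund_b < .data$abund_a ~ "down",
        TRUE ~ "flat"
      )
    ) |>
    dplyr::arrange(.data$gene_id) |>
    dplyr::select("gene_id", "comparison", "abund_a", "abund_b",
                  "fold_diff", "direction", "exclusive")
}

#' Highly differentially expressed genes
#'
#' Keeps non-exclusive genes with a fold difference at or above the
#' threshold (20-fold in the study), plus exclusive genes flagged by
#' their `exclusive` column so either tallying convention can be
#' applied; sorted by descending fold with exclusive genes last.
#'
#' @param records [compare_expression()] tibble.
#' @param threshold Fold threshold (inclusive; default 20).
#' @return Subset of `records`.
#' @export
highly_de <- function(records, threshold = 20) {
  records |>
    dplyr::filter((!.data$exclusive & .data$fold_diff >= threshold) |
                    .data$exclusive) |>
    dplyr::arrange(.data$exclusive, dplyr::desc(.data$fold_diff),
                   .data$gene_id)
}

#' Rank candidate reference genes by distance from (1,1,1)
#'
#' An unperturbed transcript has fold change 1 in every comparison, so
#' the idealized reference point in the three-comparison fold space is
#' (1,1,1); candidates are ranked by ascending Euclidean distance
#' `sqrt((x-1)^2 + (y-1)^2 + (z-1)^2)` of their absolute fold changes
#' from it. Only genes detected on both sides of all three comparisons
#' are eligible.
#'
#' @param comparisons List of three [compare_expression()] tibbles (x, y,
#'   z order: 4th vs 2nd instar, female vs male, nymph vs adult in the
#'   study).
#' @return Tibble with `gene_id`, `x`, `y`, `z`, `distance`, ascending by
#'   distance with alphabetical tie-break.
#' @export
select_reference <- function(comparisons) {
  stopifnot(length(comparisons) == 3L)
  folds <- purrr::map2(unname(comparisons), 1:3, function(cmp, i) {
    cmp |>
      dplyr::filter(!.data$exclusive) |>
      dplyr::select("gene_id", fold = "fold_diff") |>
      stats::setNames(c("gene_id", c("x", "y", "z")[i]))
  })
  eligible <- purrr::reduce(folds, dplyr::inner_join, by = "gene_id")
  if (nrow(eligible) == 0L) {
    stop("no gene is detected on both sides of all three comparisons",
         call. = FALSE)
  }
  eligible |>
    dplyr::mutate(distance = sqrt((.data$x - 1)^2 + (.data$y - 1)^2 +
                                    (.data$z - 1)^2)) |>
    dplyr::arrange(.data$distance, .data$gene_id)
}
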