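#' Delta-Ct between a target and an endogenous control
#'
#' `delta_ct = ct_target - ct_control`; relative expression under the
#' perfect-doubling model is then `2^(-delta_ct)`.
#'
#' @param target_ct,control_ct Finite positive Ct values (cycles),
#'   vectorized.
#' @return Numeric vector of delta-Ct values.
#' @export
delta_ct <- function(target_ct, control_ct) {
  if (any(!is.finite(target_ct)) || any(!is.finite(control_ct))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  target_ct - control_ct
}

#' 2^-deltaCt relative expression per sample
#'
#' For each biological replicate, the technical-replicate Cts of the
#' target and of the endogenous control are averaged, delta-Ct is taken
#' between the two means, and the replicate's relative expression is
#' `2^(-delta_ct)` (efficiency fixed at perfect doubling). Mean and
#' standard error of the mean are then computed across biological
#' replicates (`sem = sd / sqrt(n_bio)`, with the n-1 denominator sd; 0
#' for a single replicate).
#'
#' A biological replicate missing the control assay is excluded with a
#' warning; a sample with no usable replicate is an error.
#'
#' @param ct_table Ct tibble ([read_ct_table()] layout).
#' @param gene Target gene label.
#' @param control Endogenous control gene label (the study uses 18S rRNA
#'   for RNA load and endoreticulocalbin for gene expression).
#' @return Tibble with one row per sample: `gene`, `sample`,
#'   `control_gene`, `mean_rel`, `sem`, `n_bio`.
#' @export
rel_expression <- function(ct_table, gene, control) {
  sub <- dplyr::filter(ct_table, .data$gene %in% c(!!gene, !!control))
  if (!gene %in% sub$gene) {
    stop("gene '", gene, "' absent from Ct table", call. = FALSE)
  }
  if (!control %in% sub$gene) {
    stop("control '", control, "' absent from Ct table", call. = FALSE)
  }
  means <- sub |>
    dplyr::group_by(.data$sample, .data$gene, .data$biological_rep) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  target_col <- gene
  control_col <- control
  missing_ctl <- is.na(means[[control_col]]) & !is.na(means[[target_col]])
  if (any(missing_ctl)) {
    warning(sum(missing_ctl), " biological replicate(s) of '", gene,
            "' lack control Cts and were excluded", call. = FALSE)
  }
  per_rep <- means |>
    dplyr::filter(!is.na(.data[[target_col]]),
                  !is.na(.data[[control_col]])) |>
    dplyr::mutate(rel = 2^(-delta_ct(.data[[target_col]],
                                     .data[[control_col]])))
  if (nrow(per_rep) == 0L) {
    stop("no biological replicate of '", gene,
         "' has both target and control Cts", call. = FALSE)
  }
  per_rep |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      gene = !!gene,
      control_gene = !!control,
      mean_rel = mean(.data$rel),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$rel) / sqrt(dplyr::n()), 0),
      n_bio = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("gene", "sample", "control_gene", "mean_rel", "sem",
                  "n_bio")
}

#' Fold induction between a stimulated and an unstimulated condition
#'
#' Ratio of mean relative expressions, e.g. immune-induced over
#' non-induced adults of the same sex under the same endogenous control.
#'
#' @param rel [rel_expression()] tibble.
#' @param stim,unstim Sample labels of the stimulated and baseline
#'   conditions.
#' @return A single fold value.
#' @export
induction_fold <- function(rel, stim, unstim) {
  pick <- function(s) {
    v <- rel$mean_rel[rel$sample == s]
    if (length(v) != 1L) {
      stop("sample '", s, "' not uniquely present in relative-expression ",
           "table", call. = FALSE)
    }
    v
  }
  base <- pick(unstim)
  if (base == 0) {
    stop("baseline relative expression is zero; fold undefined",
         call. = FALSE)
  }
  pick(stim) / base
}
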