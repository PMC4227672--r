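#' Run the full pipeline from a configuration
#'
#' Executes the stages in dependency order — read cleaning, tier
#' classification (with gold translation), annotation transfer, per-sample
#' quantification, the three pooled pairwise comparisons, reference-gene
#' ranking, and qRT-PCR summarization — writing each stage's tables under
#' `outdir` and recording a manifest (parameter values, input checksums,
#' per-stage row counts). A stage failure stops the run with the stage
#' name and cause; outputs of completed stages remain on disk.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' blocks:
#' \preformatted{
#' samples:            # one entry per sample
#'   - {label: nymph2, fastq: n2.fastq, psl: n2.psl}
#' puts: puts.fasta
#' hits: hits.blasttab
#' mapping: map.tsv
#' ct: ct.csv
#' ct_control: ctrl_endoreticulocalbin
#' outdir: out/
#' qc: {trim_threshold: 21, min_length: 36, ...}      # optional overrides
#' tier: {gold_min_coverage: 0.90, ...}
#' quant: {min_aligned_frac: 0.95}
#' de_threshold: 20
#' }
#' Comparisons follow the study design and require the four sample
#' labels `nymph2`, `nymph4`, `adult_male`, `adult_female`.
#'
#' @param config Path to a YAML file or a named list.
#' @param outdir Output directory; overrides `config$outdir` when given.
#' @return An object of class `put_run`: a list with `manifest`,
#'   `results` (the stage tibbles) and `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("no output directory configured", call. = FALSE)

  # validate before any stage runs
  samples <- purrr::map_dfr(config$samples, tibble::as_tibble)
  need <- c("label", "fastq", "psl")
  if (!all(need %in% names(samples))) {
    stop("each sample needs label, fastq and psl entries", call. = FALSE)
  }
  if (anyDuplicated(samples$label)) {
    stop("duplicate sample labels in config", call. = FALSE)
  }
  inputs <- c(config$puts, config$hits, config$mapping, config$ct,
              samples$fastq, samples$psl)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  qc_p <- do.call(qc_params, config$qc %||% list())
  tier_p <- do.call(tier_params, config$tier %||% list())
  quant_p <- do.call(quant_params, config$quant %||% list())
  de_threshold <- config$de_threshold %||% 20

  stages <- list()
  results <- list()
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- out$rows
    results[[name]] <<- out$value
    out$value
  }

  cleaned <- run_stage("qc", {
    per_sample <- purrr::map(seq_len(nrow(samples)), function(i) {
      clean_sample(read_fastq(samples$fastq[i]), qc_p, samples$label[i])
    })
    names(per_sample) <- samples$label
    report <- dplyr::bind_rows(purrr::map(per_sample, "report"))
    report <- dplyr::bind_rows(report, qc_total(report))
    write_table(report, file.path(outdir, "qc_report.tsv"), sci = FALSE)
    for (s in samples$label) {
      write_fastq(per_sample[[s]]$reads,
                  file.path(outdir, paste0(s, ".clean.fastq")))
    }
    list(value = list(samples = per_sample, report = report),
         rows = nrow(report))
  })

  tiers <- run_stage("tier", {
    puts <- read_puts(config$puts)
    hits <- read_blast_tab(config$hits)
    assignments <- classify_tiers(puts, hits, tier_p)
    proteins <- trim_translate(puts, assignments)
    write_table(dplyr::select(assignments, -"q_start", -"q_end",
                              -"query_frame"),
                file.path(outdir, "tiers.tsv"), sci = FALSE)
    write_puts(
      dplyr::select(proteins, put_id = "put_id", sequence = "trimmed_cds"),
      file.path(outdir, "gold_cds.fasta"))
    list(value = list(assignments = assignments, proteins = proteins),
         rows = nrow(assignments))
  })

  run_stage("annotate", {
    mapping <- read_mapping_table(config$mapping)
    summaries <- purrr::map_dfr(c("gold", "silver"), function(tr) {
      if (sum(tiers$assignments$tier == tr) == 0L) return(NULL)
      annotation_summary(
        suppressMessages(transfer_terms(tiers$assignments, mapping, tr)))
    })
    write_table(summaries, file.path(outdir, "annotation_summary.tsv"),
                sci = FALSE)
    list(value = summaries, rows = nrow(summaries))
  })

  expr <- run_stage("quant", {
    per_sample <- purrr::map(seq_len(nrow(samples)), function(i) {
      s <- samples$label[i]
      total <- nrow(cleaned$samples[[s]]$reads)
      quantify_sample(read_psl(samples$psl[i]), tiers$assignments,
                      total, s, quant_p)
    })
    names(per_sample) <- samples$label
    all_expr <- dplyr::bind_rows(per_sample)
    write_table(all_expr, file.path(outdir, "expression.tsv"))
    list(value = per_sample, rows = nrow(all_expr))
  })

  comparisons <- run_stage("compare", {
    need <- c("nymph2", "nymph4", "adult_male", "adult_female")
    if (!all(need %in% names(expr))) {
      stop("comparisons require samples ", paste(need, collapse = ", "))
    }
    cmp <- list(
      n4_vs_n2 = compare_expression(expr$nymph2, expr$nymph4, "n4_vs_n2"),
      female_vs_male = compare_expression(expr$adult_male,
                                          expr$adult_female,
                                          "female_vs_male"),
      nymph_vs_adult = compare_expression(
        pool_samples(expr$nymph2, expr$nymph4, sample = "nymph"),
        pool_samples(expr$adult_male, expr$adult_female,
                     sample = "adult"),
        "nymph_vs_adult")
    )
    for (nm in names(cmp)) {
      write_table(cmp[[nm]], file.path(outdir, paste0(nm, ".tsv")))
      write_table(highly_de(cmp[[nm]], de_threshold),
                  file.path(outdir, paste0(nm, ".highly_de.tsv")))
    }
    list(value = cmp, rows = sum(vapply(cmp, nrow, integer(1))))
  })

  run_stage("refgene", {
    ranked <- select_reference(comparisons)
    write_table(ranked, file.path(outdir, "reference_genes.tsv"),
                sci = FALSE)
    list(value = ranked, rows = nrow(ranked))
  })

  run_stage("qpcr", {
    ct <- read_ct_table(config$ct)
    control <- config$ct_control %||% "ctrl_endoreticulocalbin"
    targets <- setdiff(unique(ct$gene), control)
    rel <- purrr::map_dfr(targets, function(g) {
      rel_expression(ct, g, control)
    })
    write_table(rel, file.path(outdir, "qpcr_rel_expression.tsv"),
                sci = FALSE)
    list(value = rel, rows = nrow(rel))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("puttier")),
    parameters = list(qc = unclass(qc_p), tier = unclass(tier_p),
                      quant = unclass(quant_p),
                      de_threshold = de_threshold),
    inputs = as.list(tools::md5sum(inputs)),
    stage_rows = stages
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(manifest = manifest, results = results, outdir = outdir),
            class = "put_run")
}

#' @export
print.put_run <- function(x, ...) {
  cat("<put_run> ", length(x$manifest$stage_rows), " stages -> ",
      x$outdir, "\n", sep = "")
  rows <- unlist(x$manifest$stage_rows)
  for (nm in names(rows)) {
    cat(sprintf("  %-10s %6d rows\n", nm, rows[[nm]]))
  }
  invisible(x)
}

#' Stage-level summary of a pipeline run
#'
#' @param x A `put_run` object.
#' @param ... Unused.
#' @return Tibble with one row per stage (`stage`, `rows`).
#' @exportS3Method generics::tidy
tidy.put_run <- function(x, ...) {
  tibble::tibble(stage = names(x$manifest$stage_rows),
                 rows = unlist(x$manifest$stage_rows, use.names = FALSE))
}

#' One-row summary of a pipeline run
#'
#' @param x A `put_run` object.
#' @param ... Unused.
#' @return One-row tibble: stage count, input count, output directory.
#' @exportS3Method generics::glance
glance.put_run <- function(x, ...) {
  tibble::tibble(
    n_stages = length(x$manifest$stage_rows),
    n_inputs = length(x$manifest$inputs),
    outdir = x$outdir
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
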