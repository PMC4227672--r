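#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the data structure of a four-stage insect
#' RNA-Seq study: per-sample read pools with stage-dependent gene
#' abundances, assembled transcripts whose homology hits are constructed
#' to satisfy each reliability tier's criteria exactly (boundary cases
#' included), adult-exclusive symbiont-like genes, one minimally
#' perturbed reference gene, and replicated qRT-PCR Ct tables.
#'
#' The defaults define the package's standard study conditions: 40 PUTs
#' with a 10/20/10/0 gold/silver/bronze/unclassified mix; the 10 gold
#' PUTs represent 9 distinct proteins (the stable gene carries two
#' duplicate PUTs to exercise multi-mapping ties and gene aggregation):
#' 7 genes planted with 32-40-fold differences spread over the three
#' study comparisons, one unperturbed reference gene, and one
#' adult-exclusive gene. Planted per-sample proportions are fixed
#' multiples of 5e-4 so expected counts are integers at the default
#' 20,000-read budgets; background gene abundances are log-uniform over
#' a 1e-8..1e-4 relative range and absorb the per-sample remainder so
#' sample totals match exactly (making planted fold changes exact).
#'
#' @param seed Master seed; every emitted file derives its own stream
#'   from it, so outputs are byte-identical across runs and adding one
#'   output never perturbs another.
#' @param n_puts Total number of PUTs (default 40).
#' @param tier_mix Named proportions over gold/silver/bronze/unclassified
#'   (must sum to 1; counts are rounded largest-remainder).
#' @param sample_budgets Named integer vector of cleaned-read budgets per
#'   sample; names must be `nymph2`, `nymph4`, `adult_male`,
#'   `adult_female`.
#' @param read_len Read length in bases (default 100, SE100).
#' @param n_highly_de Number of genes planted with a >= 20-fold change
#'   (default 7).
#' @param n_exclusive_adult Number of adult-only (symbiont-like) genes
#'   (default 1).
#' @param qc_fail_frac Fraction of raw reads planted to fail the
#'   cleaning rules, split across the three rules (default 0.10).
#' @param ct_noise_sd Per-well Gaussian Ct noise, cycles (default 0.1).
#' @param ct_bio_reps,ct_tech_reps Replication of the Ct table (3 x 3).
#' @param abundance_range Relative abundance range for background genes
#'   (log-uniform; default `c(1e-8, 1e-4)`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_puts = 40,
                       tier_mix = c(gold = 0.25, silver = 0.5,
                                    bronze = 0.25, unclassified = 0),
                       sample_budgets = c(nymph2 = 20000, nymph4 = 20000,
                                          adult_male = 20000,
                                          adult_female = 20000),
                       read_len = 100, n_highly_de = 7,
                       n_exclusive_adult = 1, qc_fail_frac = 0.10,
                       ct_noise_sd = 0.1, ct_bio_reps = 3,
                       ct_tech_reps = 3,
                       abundance_range = c(1e-8, 1e-4)) {
  stopifnot(abs(sum(tier_mix) - 1) < 1e-9,
            all(names(tier_mix) == tier_levels),
            setequal(names(sample_budgets),
                     c("nymph2", "nymph4", "adult_male", "adult_female")),
            all(sample_budgets > 0), read_len >= 50,
            qc_fail_frac >= 0, qc_fail_frac < 1,
            ct_noise_sd >= 0, ct_bio_reps >= 1, ct_tech_reps >= 1)
  counts <- round_to_counts(tier_mix, n_puts)
  n_gold_genes <- max(counts[["gold"]] - 1L, 0L)  # stable gene is duplicated
  if (counts[["gold"]] > 0L &&
      n_gold_genes < n_highly_de + n_exclusive_adult + 1L) {
    stop("infeasible tier_mix: ", counts[["gold"]], " gold PUTs provide ",
         n_gold_genes, " distinct genes, fewer than the ",
         n_highly_de + n_exclusive_adult + 1L,
         " planted roles (highly-DE + exclusive + stable)", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_puts = n_puts, tier_counts = counts,
         sample_budgets = sample_budgets, read_len = read_len,
         n_highly_de = n_highly_de,
         n_exclusive_adult = n_exclusive_adult,
         qc_fail_frac = qc_fail_frac, ct_noise_sd = ct_noise_sd,
         ct_bio_reps = ct_bio_reps, ct_tech_reps = ct_tech_reps,
         abundance_range = abundance_range),
    class = "sim_config"
  )
}

# Largest-remainder rounding of proportions to integer counts summing to n.
round_to_counts <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), names(props))
}

# Run code under a deterministic stream derived from (seed, label),
# restoring the caller's RNG state afterwards.
with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  set.seed((as.integer(seed) %% 1000003L) * 2017L + h %% 1000003L)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n random codons drawn from the 61 non-stop codons of the standard code.
stop_free_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(
    as.vector(outer(bases, bases, paste0)), bases, paste0))
  ok <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# Hit-metric recipes per tier. Each row satisfies exactly its tier's
# criteria (and, for gold, fails none); boundary rows sit exactly on the
# inclusive thresholds 300 nt / 100 aa / 0.75 / 0.90 / 0.30.
gold_recipes <- function() {
  tibble::tribble(
    ~subject_len, ~align_len, ~positives, ~hsp_count, ~extra_query,
    150L,         145L,       124L,       1L,         40L,
    120L,         108L,       90L,        1L,         30L,  # coverage 0.90
    110L,         104L,       78L,        1L,         32L,  # positives 0.75
    100L,         100L,       80L,        1L,         0L,   # query_len 300
    100L,         95L,        75L,        1L,         25L   # subject_len 100
  )
}

silver_recipes <- function() {
  tibble::tribble(
    ~subject_len, ~align_len, ~positives, ~hsp_count, ~query_len,
    44L,          33L,        30L,        1L,         100L,  # cov 0.75, len 100
    150L,         140L,       120L,      2L,          450L,  # multi-HSP
    120L,         112L,       80L,       1L,          366L,  # positives < 0.75
    80L,          76L,        70L,       1L,          250L,  # query < 300
    90L,          85L,        75L,       1L,          275L   # subject < 100
  )
}

bronze_recipes <- function() {
  tibble::tribble(
    ~subject_len, ~align_len, ~positives, ~hsp_count, ~query_len,
    100L,         30L,        25L,        1L,         100L,  # cov 0.30 exactly
    200L,         100L,       80L,        1L,         320L,
    150L,         60L,        45L,       1L,          200L
  )
}

# Planted per-sample proportions for the gold gene roles, in units of
# 5e-4 of a sample's cleaned reads (columns nymph2, nymph4, adult_male,
# adult_female). Fold targets are >= 32 so multinomial noise at 2e4-read
# budgets cannot drag a planted gene below the 20-fold call, and flat
# rows cannot rise to it.
gold_role_units <- function(n_de, n_excl, n_flat) {
  de_rows <- matrix(c(
    8, 320, 30, 30,    # x = 40 up
    300, 8, 30, 30,    # x = 37.5 down
    20, 20, 8, 280,    # y = 35 up
    20, 20, 256, 8,    # y = 32 down
    6, 6, 200, 200,    # z ~ 33.3 up
    160, 160, 5, 5,    # z = 32 down
    8, 256, 30, 30     # x = 32 up
  ), ncol = 4, byrow = TRUE)
  if (n_de > nrow(de_rows)) {
    de_rows <- de_rows[rep(seq_len(nrow(de_rows)),
                           length.out = n_de), , drop = FALSE]
  } else {
    de_rows <- de_rows[seq_len(n_de), , drop = FALSE]
  }
  excl_rows <- matrix(rep(c(0, 0, 30, 30), n_excl), ncol = 4, byrow = TRUE)
  if (n_excl > 1L) {
    excl_rows[, 3:4] <- excl_rows[, 3:4] - 5 * (seq_len(n_excl) - 1L)
  }
  flat_rows <- matrix(rep(c(30, 45, 36, 30), n_flat), ncol = 4,
                      byrow = TRUE)
  rbind(de_rows,
        matrix(c(40, 40, 40, 40), ncol = 4),   # stable reference gene
        excl_rows,
        if (n_flat > 0L) flat_rows)
}

#' Simulate a tiered transcriptome with planted truth
#'
#' Emits PUT sequences, a homology-hit table whose metrics satisfy each
#' planted tier's criteria exactly (including rows sitting on the
#' inclusive 300 nt / 100 aa / 0.75 / 0.90 / 0.30 boundaries), decoy
#' lower-scoring and tied hits to exercise best-hit selection, an offline
#' annotation mapping table, and the ground-truth bookkeeping the tests
#' compare against.
#'
#' @param config [sim_config()].
#' @return List with `puts`, `hits`, `mapping` (tidy tibbles in the
#'   package's reader layouts) and `truth` (list: `put_truth`,
#'   `gene_props`, `fold_truth`, `stable_gene`, `exclusive_genes`,
#'   `term_truth`, `qpcr_truth`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$tier_counts
  with_stream(config$seed, "transcriptome", {
    tiers <- sample(rep(tier_levels, counts))
    put_ids <- sprintf("PUT%04d", seq_len(config$n_puts))
    gold_idx <- which(tiers == "gold")
    n_gold <- length(gold_idx)
    n_gold_genes <- max(n_gold - 1L, 0L)
    n_de <- config$n_highly_de
    n_excl <- config$n_exclusive_adult
    n_flat <- n_gold_genes - n_de - n_excl - 1L

    # Gene roles, in the lexicographic order of their subject ids: the
    # stable gene owns two PUTs (the first two gold slots).
    roles <- c(paste0("de", seq_len(n_de)), "stable",
               if (n_excl > 0L) paste0("exclusive", seq_len(n_excl)),
               if (n_flat > 0L) paste0("flat", seq_len(n_flat)))
    gold_subjects <- sprintf("gb|SYNP%03d.1|", seq_len(n_gold_genes))
    units <- gold_role_units(n_de, n_excl, max(n_flat, 0L))
    gene_props <- tibble::tibble(
      gene_id = rep(gold_subjects, each = 4L),
      role = rep(roles, each = 4L),
      sample = rep(c("nymph2", "nymph4", "adult_male", "adult_female"),
                   n_gold_genes),
      proportion = as.vector(t(units)) * 5e-4
    )
    stable_gene <- gold_subjects[roles == "stable"]
    put_subject <- character(config$n_puts)
    if (n_gold > 0L) {
      # Stable gene's duplicate PUT occupies the first gold slot.
      put_subject[gold_idx] <- c(stable_gene, gold_subjects)
    }
    silver_idx <- which(tiers == "silver")
    bronze_idx <- which(tiers == "bronze")
    put_subject[silver_idx] <-
      sprintf("gb|SYNS%03d.1|", seq_along(silver_idx))
    put_subject[bronze_idx] <-
      sprintf("gb|SYNB%03d.1|", seq_along(bronze_idx))

    # Build hits and sequences per PUT from the tier recipes.
    seqs <- character(config$n_puts)
    hit_rows <- vector("list", config$n_puts)
    g_rec <- gold_recipes(); s_rec <- silver_recipes()
    b_rec <- bronze_recipes()
    k_gold <- 0L; k_silver <- 0L; k_bronze <- 0L
    for (i in seq_len(config$n_puts)) {
      tier_i <- tiers[i]
      if (tier_i == "unclassified") {
        seqs[i] <- random_dna(sample(150:600, 1L))
        next
      }
      if (tier_i == "gold") {
        k_gold <- k_gold + 1L
        r <- g_rec[(k_gold - 1L) %% nrow(g_rec) + 1L, ]
        span <- 3L * r$align_len
        frame <- c(1L, 2L, -1L)[(k_gold - 1L) %% 3L + 1L]
        lead <- if (r$extra_query == 0L) 0L else
          sample(seq_len(r$extra_query), 1L) - 1L
        cds <- stop_free_cds(r$align_len)
        region <- if (frame < 0L) {
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cds)))
        } else cds
        seqs[i] <- paste0(
          if (lead > 0L) random_dna(lead) else "",
          region,
          if (r$extra_query - lead > 0L)
            random_dna(r$extra_query - lead) else ""
        )
        q_start <- lead + 1L
        q_end <- lead + span
        query_len <- span + r$extra_query
      } else if (tier_i == "silver") {
        k_silver <- k_silver + 1L
        r <- s_rec[(k_silver - 1L) %% nrow(s_rec) + 1L, ]
        query_len <- r$query_len
        span <- 3L * r$align_len
        q_start <- sample(seq_len(query_len - span + 1L), 1L)
        q_end <- q_start + span - 1L
        frame <- 1L
        seqs[i] <- random_dna(query_len)
      } else {
        k_bronze <- k_bronze + 1L
        r <- b_rec[(k_bronze - 1L) %% nrow(b_rec) + 1L, ]
        query_len <- r$query_len
        span <- 3L * r$align_len
        q_start <- sample(seq_len(query_len - span + 1L), 1L)
        q_end <- q_start + span - 1L
        frame <- 1L
        seqs[i] <- random_dna(query_len)
      }
      hit_rows[[i]] <- tibble::tibble(
        put_id = put_ids[i], subject_id = put_subject[i],
        subject_desc = paste("synthetic", tier_i, "protein",
                             put_subject[i]),
        query_len = as.integer(query_len),
        subject_len = as.integer(r$subject_len),
        hsp_count = as.integer(r$hsp_count),
        align_len = as.integer(r$align_len),
        positives = as.integer(r$positives),
        identity_pct = round(stats::runif(1, 60, 95), 2),
        bit_score = round(stats::runif(1, 180, 260), 1),
        e_value = 1e-50,
        q_start = as.integer(q_start), q_end = as.integer(q_end),
        query_frame = as.integer(frame)
      )
    }
    hits <- dplyr::bind_rows(hit_rows)

    # Decoys: every third classified PUT gets a lower-scoring bronze-like
    # hit that best-hit selection must discard; every fifth gets a hit
    # tied on bit score and E-value whose subject id sorts later, so the
    # lexicographic tie-break keeps the planted hit.
    classified <- hits$put_id
    low <- hits[seq_along(classified) %% 3L == 0L, ]
    if (nrow(low) > 0L) {
      low$subject_id <- sprintf("gb|ZDEC%03d.1|", seq_len(nrow(low)))
      low$subject_desc <- "synthetic decoy protein"
      low$bit_score <- low$bit_score - 100
      low$e_value <- 1e-5
      low$subject_len <- 400L
      low$align_len <- pmin(80L, low$align_len)
      low$positives <- pmin(low$positives, low$align_len)
      low$q_end <- low$q_start + 3L * low$align_len - 1L
    }
    tied <- hits[seq_along(classified) %% 5L == 0L, ]
    if (nrow(tied) > 0L) {
      tied$subject_id <- sprintf("gb|ZTIE%03d.1|", seq_len(nrow(tied)))
      tied$subject_desc <- "synthetic tied decoy"
      tied$subject_len <- 500L
      tied$align_len <- pmin(60L, tied$align_len)
      tied$positives <- pmin(tied$positives, tied$align_len)
      tied$q_end <- tied$q_start + 3L * tied$align_len - 1L
    }
    hits <- dplyr::bind_rows(hits, low, tied)
    # File order: grouped per query, planted hit first.
    hits <- hits[order(match(hits$put_id, put_ids)), ]

    puts <- tibble::tibble(put_id = put_ids, sequence = seqs,
                           length = nchar(seqs))

    mapping <- build_mapping(put_subject, tiers)

    fold_truth <- true_folds(gene_props)
    truth <- list(
      put_truth = tibble::tibble(put_id = put_ids, tier = tiers,
                                 gene_id = dplyr::na_if(put_subject, "")),
      gene_props = gene_props,
      fold_truth = fold_truth,
      stable_gene = stable_gene,
      exclusive_genes = gold_subjects[startsWith(roles, "exclusive")],
      highly_de_genes = fold_truth$gene_id[
        !fold_truth$exclusive &
          pmax(fold_truth$x, fold_truth$y, fold_truth$z) >= 20],
      term_truth = attr(mapping, "term_truth"),
      qpcr_truth = tibble::tibble(
        gene = "tgt_clectin", control = "ctrl_endoreticulocalbin",
        condition = c("induced_male", "induced_female"),
        baseline = c("adult_male", "adult_female"),
        fold = c(4, 2)
      )
    )
    list(puts = puts, hits = hits, mapping = mapping, truth = truth)
  })
}

# True fold changes of the three study comparisons from planted
# proportions. Sample weight totals are equalized by the background
# genes, so proportion ratios are exact.
true_folds <- function(gene_props) {
  wide <- tidyr::pivot_wider(gene_props, names_from = "sample",
                             values_from = "proportion")
  fold <- function(a, b) {
    dplyr::case_when(
      xor(a == 0, b == 0) ~ 0,
      a == 0 & b == 0 ~ 1,
      TRUE ~ pmax(a, b) / pmin(a, b)
    )
  }
  nym <- (wide$nymph2 + wide$nymph4) / 2
  adu <- (wide$adult_male + wide$adult_female) / 2
  tibble::tibble(
    gene_id = wide$gene_id, role = wide$role,
    x = fold(wide$nymph2, wide$nymph4),
    y = fold(wide$adult_male, wide$adult_female),
    z = fold(nym, adu),
    exclusive = xor(wide$nymph2 == 0, wide$nymph4 == 0) |
      xor(wide$adult_male == 0, wide$adult_female == 0) |
      xor(nym == 0, adu == 0)
  )
}

# Offline mapping table: ~2/3 of gold and silver subjects mapped, with
# small term sets drawn from fixed pools; truth records the per-subject
# term assignments.
build_mapping <- function(put_subject, tiers) {
  subjects <- tibble::tibble(subject_id = put_subject, tier = tiers) |>
    dplyr::filter(nzchar(.data$subject_id),
                  .data$tier %in% c("gold", "silver")) |>
    dplyr::distinct(.data$subject_id, .data$tier)
  n <- nrow(subjects)
  mapped <- seq_len(n) %% 3L != 0L   # 2 of every 3 subjects mapped
  pfam_pool <- sprintf("PF%05d", 1:12)
  go_pool <- sprintf("GO:%07d", 3700 + 1:10)
  kegg_pool <- sprintf("K%05d", 1:8)
  rows <- purrr::map(seq_len(n), function(i) {
    if (!mapped[i]) {
      return(tibble::tibble(
        nr_id = subjects$subject_id[i], uniprot_acc = NA_character_,
        go_mf = list(character(0)), go_other = list(character(0)),
        pfam = list(character(0)), kegg = list(character(0))
      ))
    }
    tibble::tibble(
      nr_id = subjects$subject_id[i],
      uniprot_acc = sprintf("Q%05d", i),
      go_mf = list(sample(go_pool, sample(1:3, 1L))),
      go_other = list(sample(sprintf("GO:%07d", 8100 + 1:6),
                             sample(0:2, 1L))),
      pfam = list(sample(pfam_pool, sample(1:3, 1L))),
      kegg = list(sample(kegg_pool, sample(0:2, 1L)))
    )
  })
  mapping <- dplyr::bind_rows(rows)
  term_truth <- tibble::tibble(
    subject_id = subjects$subject_id, tier = subjects$tier,
    mapped = mapped,
    pfam = mapping$pfam, go_mf = mapping$go_mf
  )
  structure(mapping, term_truth = term_truth)
}

#' Simulate per-sample reads and the alignments a perfect aligner yields
#'
#' Draws each sample's reads multinomially over genes with the planted
#' abundances (or deterministically at their expectations), and emits
#' both the raw read tibbles (including reads planted to fail each
#' cleaning rule at a known rate) and the alignment records an exact
#' aligner would produce against the gold PUTs: full-length
#' 100%-identity alignments for gold-gene reads, duplicate-PUT ties for
#' the stable gene, plus planted sub-95%-span and one-mismatch
#' alignments that quantification must reject.
#'
#' @param config [sim_config()].
#' @param sim [simulate_transcriptome()] output.
#' @param sampling `"multinomial"` (default) or `"expected"` (noise-free
#'   counts at the planted expectations; fold recovery is then exact).
#' @param emit_reads Logical: also build the raw read tibbles (FASTQ
#'   content). Alignments and counts do not require them.
#' @return List with per-sample elements `reads` (raw read tibble or
#'   `NULL`), `alignments` ([read_psl()] layout), `total_reads` (cleaned
#'   budget), and a `counts` tibble of the drawn per-gene read counts
#'   (`gene_id`, `sample`, `count`, `expected`).
#' @export
simulate_reads <- function(config, sim,
                           sampling = c("multinomial", "expected"),
                           emit_reads = TRUE) {
  sampling <- match.arg(sampling)
  truth <- sim$truth
  gold_puts <- truth$put_truth |>
    dplyr::filter(.data$tier == "gold") |>
    dplyr::arrange(.data$put_id)
  samples <- names(config$sample_budgets)
  out <- list()
  count_rows <- list()
  for (s in samples) {
    budget <- as.integer(config$sample_budgets[[s]])
    props <- truth$gene_props |>
      dplyr::filter(.data$sample == s) |>
      dplyr::arrange(.data$gene_id)
    res <- with_stream(config$seed, paste0("reads_", s), {
      sample_read_set(config, s, budget, props, gold_puts, sampling,
                      emit_reads)
    })
    out[[s]] <- res[c("reads", "alignments", "total_reads")]
    count_rows[[s]] <- res$counts
  }
  c(out, list(counts = dplyr::bind_rows(count_rows)))
}

# One sample's reads + alignments. Gold genes get their planted
# proportions; background genes share the remainder with log-uniform
# relative weights.
sample_read_set <- function(config, s, budget, props, gold_puts,
                            sampling, emit_reads) {
  n_bg <- 30L
  bg_w <- exp(stats::runif(n_bg, log(config$abundance_range[1L]),
                           log(config$abundance_range[2L])))
  bg_p <- (1 - sum(props$proportion)) * bg_w / sum(bg_w)
  p <- c(props$proportion, bg_p)
  gene_ids <- c(props$gene_id, sprintf("bg%03d", seq_len(n_bg)))
  if (sampling == "multinomial") {
    counts <- as.integer(stats::rmultinom(1L, budget, p))
  } else {
    counts <- floor(p * budget)
    short <- budget - sum(counts)
    if (short > 0L) {
      # planted gold expectations are integral; remainder goes to the
      # background genes with the largest fractional parts
      frac <- p * budget - counts
      frac[seq_len(nrow(props))] <- -1
      extra <- order(frac, decreasing = TRUE)[seq_len(short)]
      counts[extra] <- counts[extra] + 1L
    }
    counts <- as.integer(counts)
  }
  gene_of_read <- rep(gene_ids, counts)
  read_ids <- sprintf("%s_r%06d", s, seq_len(budget))

  # Alignments for gold-gene reads: one row per PUT of the read's gene.
  put_by_gene <- split(gold_puts$put_id, gold_puts$gene_id)
  is_gold_read <- gene_of_read %in% names(put_by_gene)
  gold_read_ids <- read_ids[is_gold_read]
  gold_read_genes <- gene_of_read[is_gold_read]
  n_puts_per <- lengths(put_by_gene)[gold_read_genes]
  aln <- tibble::tibble(
    read_id = rep(gold_read_ids, n_puts_per),
    put_id = unlist(put_by_gene[gold_read_genes], use.names = FALSE),
    matches = config$read_len, mismatches = 0L,
    read_len = config$read_len,
    q_start0 = 0L, q_end0 = config$read_len
  )
  # Boundary qualifiers: every 17th gold read aligns over exactly 95% of
  # its length ("not less than 95%" is inclusive, so it still counts).
  span95 <- as.integer(ceiling(0.95 * config$read_len))
  bnd <- which(match(aln$read_id, gold_read_ids) %% 17L == 0L)
  aln$q_end0[bnd] <- span95
  aln$matches[bnd] <- span95
  # Planted rejects (never alter counts): every 13th gold read gains a
  # one-mismatch decoy row; every 11th a sub-95% span row; and 50
  # background reads get only a sub-95% alignment.
  uniq <- tibble::tibble(read_id = gold_read_ids, gene = gold_read_genes)
  # target PUT for decoy rows; rejected regardless, so any gold PUT works
  other_put <- function(g) {
    gold_puts$put_id[1L + (seq_along(g) %% nrow(gold_puts))]
  }
  mm <- uniq[seq_len(nrow(uniq)) %% 13L == 0L, ]
  mm_rows <- if (nrow(mm) > 0L) tibble::tibble(
    read_id = mm$read_id, put_id = other_put(mm$gene),
    matches = config$read_len - 1L, mismatches = 1L,
    read_len = config$read_len, q_start0 = 0L, q_end0 = config$read_len
  )
  sh <- uniq[seq_len(nrow(uniq)) %% 11L == 0L, ]
  short_span <- as.integer(floor(0.94 * config$read_len))
  sh_rows <- if (nrow(sh) > 0L) tibble::tibble(
    read_id = sh$read_id, put_id = other_put(sh$gene),
    matches = short_span, mismatches = 0L,
    read_len = config$read_len, q_start0 = 0L, q_end0 = short_span
  )
  bg_ids <- read_ids[!is_gold_read]
  bg_reject <- utils::head(bg_ids, 50L)
  bg_rows <- if (length(bg_reject) > 0L && nrow(gold_puts) > 0L) {
    tibble::tibble(
      read_id = bg_reject, put_id = gold_puts$put_id[1L],
      matches = short_span, mismatches = 0L,
      read_len = config$read_len, q_start0 = 0L, q_end0 = short_span
    )
  }
  aln <- dplyr::bind_rows(aln, mm_rows, sh_rows, bg_rows) |>
    dplyr::mutate(aligned_len = .data$q_end0 - .data$q_start0,
                  score = as.numeric(.data$matches - .data$mismatches)) |>
    dplyr::select("read_id", "put_id", "matches", "mismatches",
                  "read_len", "aligned_len", "score") |>
    dplyr::arrange(.data$read_id, .data$put_id)

  reads <- if (emit_reads) build_sample_reads(config, s, read_ids)

  counts <- tibble::tibble(
    gene_id = props$gene_id, sample = s,
    count = counts[seq_len(nrow(props))],
    expected = props$proportion * budget
  )
  list(reads = reads, alignments = aln, total_reads = budget,
       counts = counts)
}

# Raw reads for one sample: `budget` clean survivors plus planted
# failures for each cleaning rule, at config$qc_fail_frac of raw reads.
build_sample_reads <- function(config, s, read_ids) {
  L <- config$read_len
  budget <- length(read_ids)
  n_fail <- round(budget * config$qc_fail_frac / (1 - config$qc_fail_frac))
  # vectorized sequence generation: windows into one long random string
  pool_len <- 200000L
  pool <- random_dna(pool_len)
  starts <- sample.int(pool_len - L, budget + n_fail, replace = TRUE)
  seqs <- substring(pool, starts, starts + L - 1L)
  qpool <- paste(intToUtf8(33L + sample(21:40, pool_len, replace = TRUE),
                           multiple = TRUE), collapse = "")
  qstarts <- sample.int(pool_len - L, budget + n_fail, replace = TRUE)
  quals <- substring(qpool, qstarts, qstarts + L - 1L)
  # a third of the survivors get trimmable low-quality tails (Q15) that
  # leave a core comfortably above the length floor
  low <- intToUtf8(33L + 15L)
  tail_n <- sample.int(10L, budget, replace = TRUE)
  has_tail <- seq_len(budget) %% 3L == 0L
  quals[seq_len(budget)][has_tail] <- paste0(
    substr(quals[seq_len(budget)][has_tail], 1L,
           L - tail_n[has_tail]),
    strrep(low, tail_n[has_tail])
  )
  # every 7th survivor carries one interior Q20 base, which survives the
  # fraction filter (1% < 10%) but must be masked to 'N'
  low20 <- intToUtf8(33L + 20L)
  maskable <- seq_len(budget) %% 7L == 0L
  mid <- L %/% 2L
  quals[seq_len(budget)][maskable] <- paste0(
    substr(quals[seq_len(budget)][maskable], 1L, mid - 1L), low20,
    substr(quals[seq_len(budget)][maskable], mid + 1L, L)
  )
  # planted failures, cycling the three rules:
  #  1. trimmed length < 36 (high-quality core of 20)
  #  2. >= 10% of bases at Q <= 20 (interior, so trimming keeps them)
  #  3. every base below the trim threshold (empty after trimming)
  if (n_fail > 0L) {
    kind <- seq_len(n_fail) %% 3L
    f_qual <- character(n_fail)
    side <- (L - 20L) %/% 2L
    f_qual[kind == 1L] <- paste0(strrep(low, side), strrep("I", 20L),
                                 strrep(low, L - 20L - side))
    n_bad <- ceiling(0.10 * L)
    good_run <- strrep("I", floor((L - n_bad) / (n_bad + 1L)))
    unit <- paste0(good_run, low)
    base <- strrep(unit, n_bad)
    pad <- strrep("I", L - nchar(base))
    f_qual[kind == 2L] <- paste0("I", base,
                                 strrep("I", max(0L, L - 1L - nchar(base))))
    f_qual[kind == 2L] <- substr(f_qual[kind == 2L], 1L, L)
    f_qual[kind == 0L] <- strrep(low, L)
    quals[budget + seq_len(n_fail)] <- f_qual
  }
  ids <- c(read_ids, sprintf("%s_fail%05d", s, seq_len(n_fail)))
  tibble::tibble(
    read_id = ids, sequence = seqs,
    qualities = lapply(quals, function(q) utf8ToInt(q) - 33L)
  )
}

#' Simulate a replicated qRT-PCR Ct table with planted inductions
#'
#' Wells follow `Ct = base_ct - log2(relative abundance) + N(0, sd)`;
#' control genes have constant relative abundance across conditions. The
#' planted target is 4-fold induced in immune-induced males and 2-fold
#' in females relative to the matching non-induced adults, so
#' [induction_fold()] on noise-free tables returns those folds exactly.
#'
#' @param config [sim_config()] (`ct_noise_sd = 0` gives the noise-free
#'   table).
#' @param sim [simulate_transcriptome()] output (carries `qpcr_truth`).
#' @return Ct tibble in the [read_ct_table()] layout.
#' @export
simulate_ct <- function(config, sim) {
  conditions <- c("egg", "nymph2", "nymph4", "adult_female", "adult_male",
                  "induced_male", "induced_female")
  rel <- list(
    ctrl_18s = stats::setNames(rep(1, 7), conditions),
    ctrl_endoreticulocalbin = stats::setNames(rep(1, 7), conditions),
    tgt_clectin = c(egg = 0.5, nymph2 = 1, nymph4 = 1, adult_female = 1,
                    adult_male = 1, induced_male = 4, induced_female = 2)
  )
  base_ct <- c(ctrl_18s = 12, ctrl_endoreticulocalbin = 22,
               tgt_clectin = 26)
  grid <- tidyr::expand_grid(
    sample = conditions, gene = names(rel),
    biological_rep = seq_len(config$ct_bio_reps),
    technical_rep = seq_len(config$ct_tech_reps)
  )
  with_stream(config$seed, "ct", {
    grid$ct <- base_ct[grid$gene] -
      log2(purrr::map2_dbl(grid$gene, grid$sample,
                           function(g, s) rel[[g]][[s]])) +
      stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
    grid
  })
}

#' Write a simulated data set to disk as the pipeline's input files
#'
#' Emits `puts.fasta`, `hits.blasttab`, `map.tsv`, `<sample>.fastq`,
#' `<sample>.psl`, `ct.csv` and `truth.json` under `dir`. With a fixed
#' seed the files are byte-identical across runs.
#'
#' @param config [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of the paths written, invisibly.
#' @export
write_fixture <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_transcriptome(config)
  reads <- simulate_reads(config, sim)
  ct <- simulate_ct(config, sim)
  paths <- list(
    puts = file.path(dir, "puts.fasta"),
    hits = file.path(dir, "hits.blasttab"),
    mapping = file.path(dir, "map.tsv"),
    ct = file.path(dir, "ct.csv")
  )
  write_puts(sim$puts, paths$puts)
  readr::write_tsv(
    stats::setNames(
      tibble::as_tibble(sim$hits)[, c("put_id", "subject_id",
        "subject_desc", "query_len", "subject_len", "hsp_count",
        "align_len", "positives", "identity_pct", "bit_score", "e_value",
        "q_start", "q_end", "query_frame")],
      blast_tab_cols),
    paths$hits, col_names = FALSE, progress = FALSE)
  flat_map <- sim$mapping |>
    dplyr::mutate(dplyr::across(c("go_mf", "go_other", "pfam", "kegg"),
                                ~ vapply(.x, paste, character(1),
                                         collapse = ";")),
                  uniprot_acc = dplyr::coalesce(.data$uniprot_acc, ""))
  readr::write_tsv(flat_map, paths$mapping, progress = FALSE)
  readr::write_csv(
    dplyr::rename(ct, biorep = "biological_rep",
                  techrep = "technical_rep"),
    paths$ct, progress = FALSE)
  for (s in names(config$sample_budgets)) {
    fq <- file.path(dir, paste0(s, ".fastq"))
    psl <- file.path(dir, paste0(s, ".psl"))
    write_fastq(reads[[s]]$reads, fq)
    write_psl(reads[[s]]$alignments, psl)
    paths[[paste0("fastq_", s)]] <- fq
    paths[[paste0("psl_", s)]] <- psl
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(stable_gene = sim$truth$stable_gene,
         exclusive_genes = sim$truth$exclusive_genes,
         highly_de_genes = sim$truth$highly_de_genes,
         fold_truth = sim$truth$fold_truth,
         gene_props = sim$truth$gene_props,
         qpcr_truth = sim$truth$qpcr_truth),
    truth_path, auto_unbox = TRUE, digits = NA)
  paths$truth <- truth_path
  invisible(paths)
}

#' Write alignments as a 21-column PSL file
#'
#' Inverse of [read_psl()] for the columns the pipeline consumes;
#' remaining PSL columns are filled with consistent placeholder values.
#'
#' @param alignments Alignment tibble ([read_psl()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(alignments, path) {
  n <- nrow(alignments)
  aligned <- alignments$aligned_len
  rep_n <- alignments$matches + alignments$mismatches
  ns <- pmax(aligned - rep_n, 0L)
  df <- data.frame(
    matches = alignments$matches, misMatches = alignments$mismatches,
    repMatches = 0L, nCount = ns, qNumInsert = 0L, qBaseInsert = 0L,
    tNumInsert = 0L, tBaseInsert = 0L, strand = "+",
    qName = alignments$read_id, qSize = alignments$read_len,
    qStart = 0L, qEnd = aligned,
    tName = alignments$put_id, tSize = 1000L, tStart = 0L, tEnd = aligned,
    blockCount = 1L, blockSizes = paste0(aligned, ","),
    qStarts = "0,", tStarts = "0,"
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
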