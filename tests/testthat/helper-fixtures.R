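# In-code fixtures and independent brute-force oracles shared by the
# suite. Oracles re-implement the rules as plain per-record loops so they
# stay independent of the vectorized pipeline code they check.

# one read tibble row
make_read <- function(id, seq, quals) {
  tibble::tibble(read_id = id, sequence = seq, qualities = list(quals))
}

# n random reads with qualities spanning both sides of every QC threshold
random_reads <- function(n, len_range = c(20, 60), q_range = c(2, 40)) {
  purrr::map_dfr(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    make_read(sprintf("r%04d", i),
              paste(sample(c("A", "C", "G", "T"), len, TRUE),
                    collapse = ""),
              sample(q_range[1]:q_range[2], len, TRUE))
  })
}

# brute-force per-read application of the three cleaning rules
oracle_clean <- function(reads, params = qc_params()) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    q <- reads$qualities[[i]]
    s <- strsplit(reads$sequence[i], "")[[1]]
    # terminal clipping by scanning
    a <- 1L
    while (a <= length(q) && q[a] < params$trim_threshold) a <- a + 1L
    b <- length(q)
    while (b >= a && q[b] < params$trim_threshold) b <- b - 1L
    if (a > b) next
    q <- q[a:b]; s <- s[a:b]
    if (length(q) < params$min_length) next
    if (sum(q <= params$bad_base_threshold) / length(q) >=
          params$bad_fraction) next
    s[q < params$mask_threshold] <- params$mask_symbol
    out[[length(out) + 1L]] <- make_read(reads$read_id[i],
                                         paste(s, collapse = ""), q)
  }
  if (length(out) == 0L) {
    reads[0, ]
  } else {
    dplyr::bind_rows(out)
  }
}

# brute-force best-alignment read assignment over an unindexed list
oracle_assign <- function(alignments, params = quant_params()) {
  rows <- list()
  for (id in unique(alignments$read_id)) {
    sub <- alignments[alignments$read_id == id, ]
    ok <- logical(nrow(sub))
    for (j in seq_len(nrow(sub))) {
      ok[j] <- sub$aligned_len[j] >=
        params$min_aligned_frac * sub$read_len[j] &&
        sub$mismatches[j] == 0 && sub$matches[j] == sub$aligned_len[j]
    }
    sub <- sub[ok, ]
    if (nrow(sub) == 0L) next
    best <- sub[sub$score == max(sub$score), ]
    best <- best[order(best$put_id), ][1, ]
    rows[[length(rows) + 1L]] <- best[, c("read_id", "put_id")]
  }
  dplyr::bind_rows(rows)
}

# brute-force re-derivation of a tier label from raw hit metrics
oracle_tier <- function(hit) {
  if (is.null(hit)) return("unclassified")
  cov <- hit$align_len / hit$subject_len
  pos <- hit$positives / hit$align_len
  if (hit$hsp_count == 1 && hit$query_len >= 300 &&
        hit$subject_len >= 100 && pos >= 0.75 && cov >= 0.90) {
    return("gold")
  }
  if (hit$query_len >= 100 && cov >= 0.75) return("silver")
  if (hit$query_len >= 100 && cov >= 0.30) return("bronze")
  "unclassified"
}

# minimal valid hit row; override any field through ...
make_hit <- function(put_id = "P1", subject_id = "gb|S1|", query_len = 350L,
                     subject_len = 120L, hsp_count = 1L, align_len = 118L,
                     positives = 100L, bit_score = 200, e_value = 1e-30,
                     q_start = 1L, q_end = NULL, query_frame = 1L, ...) {
  q_end <- q_end %||% min(query_len, q_start + 3L * align_len - 1L)
  tibble::tibble(
    put_id = put_id, subject_id = subject_id,
    subject_desc = "fixture protein", query_len = query_len,
    subject_len = subject_len, hsp_count = hsp_count,
    align_len = align_len, positives = positives, identity_pct = 80,
    bit_score = bit_score, e_value = e_value, q_start = q_start,
    q_end = q_end, query_frame = query_frame, ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expression table row builder
make_expr <- function(gene_id, count, total, sample = "s") {
  tibble::tibble(gene_id = gene_id, sample = sample, count = count,
                 total_reads = total, normalized = count / total)
}

# default study-condition simulation shared across tests
default_sim <- function(seed = 42) {
  cfg <- sim_config(seed = seed)
  list(config = cfg, sim = simulate_transcriptome(cfg))
}
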