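make_aln <- function(read_id, put_id, matches, mismatches = 0L,
                     read_len = 100L, aligned_len = NULL) {
  aligned_len <- aligned_len %||% (matches + mismatches)
  tibble::tibble(read_id = read_id, put_id = put_id,
                 matches = as.integer(matches),
                 mismatches = as.integer(mismatches),
                 read_len = as.integer(read_len),
                 aligned_len = as.integer(aligned_len),
                 score = matches - mismatches)
}

test_that("counting admits only near-full-length perfect alignments", {
  aln <- dplyr::bind_rows(
    make_aln("r1", "P1", 96),                 # kept
    make_aln("r2", "P1", 94),                 # span too short
    make_aln("r3", "P1", 99, 1),              # one mismatch
    make_aln("r4", "P1", 95),                 # exactly 95%, inclusive
    make_aln("r5", "P1", 90, 0, aligned_len = 96)  # unmatched aligned base
  )
  kept <- qualifying_alignments(aln)
  expect_equal(kept$read_id, c("r1", "r4"))
})

test_that("each read goes to its best-scoring PUT with lexicographic ties", {
  aln <- dplyr::bind_rows(
    make_aln("r1", "P_a", 98), make_aln("r1", "P_b", 96),
    make_aln("r2", "P_b", 97), make_aln("r2", "P_a", 97)
  )
  a <- assign_reads(qualifying_alignments(aln))
  expect_equal(a$put_id[a$read_id == "r1"], "P_a")
  expect_equal(a$put_id[a$read_id == "r2"], "P_a")
  none <- assign_reads(qualifying_alignments(make_aln("r9", "P1", 80)))
  expect_equal(nrow(none), 0L)
})

test_that("gene aggregation sums PUT counts and normalizes by total reads", {
  assignments <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    put_id = c("P1", "P1", "P1", "P2", "P2")
  )
  put_to_gene <- tibble::tibble(put_id = c("P1", "P2", "P3"),
                                gene_id = c("G", "G", "H"))
  expr <- aggregate_to_genes(assignments, put_to_gene, 100L, "s")
  expect_equal(expr$count[expr$gene_id == "G"], 5L)
  expect_equal(expr$count[expr$gene_id == "H"], 0L)   # materialized zero
  expect_equal(expr$normalized[expr$gene_id == "G"], 0.05)
  expect_error(aggregate_to_genes(assignments, put_to_gene, 0L, "s"),
               "positive")
})

test_that("unit counts over the study's cleaned totals match its tables", {
  put_to_gene <- tibble::tibble(put_id = "P1", gene_id = "G")
  one_read <- tibble::tibble(read_id = "r1", put_id = "P1")
  n2 <- aggregate_to_genes(one_read, put_to_gene, 113365193L, "nymph2")
  n4 <- aggregate_to_genes(one_read, put_to_gene, 105109728L, "nymph4")
  expect_equal(render_sci(n2$normalized), "8.82E-09")
  expect_equal(render_sci(n4$normalized), "9.51E-09")
})

test_that("assigned reads are conserved through aggregation", {
  sim <- default_sim()$sim
  cfg <- sim_config(seed = 42)
  rd <- simulate_reads(cfg, sim, emit_reads = FALSE)
  ass <- classify_tiers(sim$puts, sim$hits)
  aln <- rd$nymph4$alignments
  qual <- qualifying_alignments(aln)
  assigned <- assign_reads(qual)
  expr <- quantify_sample(aln, ass, rd$nymph4$total_reads, "nymph4")
  expect_equal(sum(expr$count), nrow(assigned))
  expect_lte(nrow(assigned), dplyr::n_distinct(qual$read_id))
  expect_lte(sum(expr$count), rd$nymph4$total_reads)
})

test_that("assignment is invariant to input row order", {
  set.seed(77)
  aln <- dplyr::bind_rows(purrr::map(1:300, function(i) {
    make_aln(sprintf("r%03d", sample(100, 1)),
             sprintf("P%d", sample(5, 1)),
             sample(90:100, 1), sample(0:1, 1))
  }))
  a1 <- assign_reads(qualifying_alignments(aln))
  a2 <- assign_reads(qualifying_alignments(aln[sample(nrow(aln)), ]))
  expect_equal(a1, a2)
})

test_that("streaming assignment agrees with a brute-force search", {
  set.seed(78)
  aln <- dplyr::bind_rows(purrr::map(1:1000, function(i) {
    make_aln(sprintf("r%03d", sample(250, 1)),
             sprintf("P%d", sample(8, 1)),
             sample(88:100, 1), sample(0:1, 1))
  }))
  fast <- assign_reads(qualifying_alignments(aln))
  slow <- oracle_assign(aln)
  expect_equal(dplyr::arrange(fast, read_id),
               dplyr::arrange(slow, read_id))
})
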