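make_put <- function(put_id, len) {
  tibble::tibble(put_id = put_id,
                 sequence = strrep("A", len), length = len)
}

test_that("best-hit selection maximizes bit score with declared tie-breaks", {
  hits <- dplyr::bind_rows(
    make_hit(bit_score = 50, subject_id = "gb|C1|"),
    make_hit(bit_score = 120, subject_id = "gb|B1|"),
    make_hit(bit_score = 80, subject_id = "gb|A1|")
  )
  expect_equal(best_hits(hits)$subject_id, "gb|B1|")
  expect_equal(best_hits(hits[1, ])$subject_id, "gb|C1|")
  tie <- dplyr::bind_rows(
    make_hit(bit_score = 100, subject_id = "gb|B1|"),
    make_hit(bit_score = 100, subject_id = "gb|A1|")
  )
  expect_equal(best_hits(tie)$subject_id, "gb|A1|")
  # lower E-value precedes the lexicographic rule
  tie_e <- dplyr::bind_rows(
    make_hit(bit_score = 100, e_value = 1e-10, subject_id = "gb|B1|"),
    make_hit(bit_score = 100, e_value = 1e-40, subject_id = "gb|Z1|")
  )
  expect_equal(best_hits(tie_e)$subject_id, "gb|Z1|")
})

test_that("tier criteria follow the inclusive gold/silver/bronze rules", {
  classify_one <- function(hit, len = hit$query_len) {
    as.character(classify_tiers(make_put(hit$put_id, len), hit)$tier)
  }
  gold <- make_hit(query_len = 350L, subject_len = 120L, align_len = 118L,
                   positives = 100L)
  expect_equal(classify_one(gold), "gold")
  # same alignment on a 250 nt query: gold length fails, coverage holds
  expect_equal(classify_one(make_hit(query_len = 250L, subject_len = 120L,
                                     align_len = 118L, positives = 100L,
                                     q_end = 250L)), "silver")
  expect_equal(classify_one(make_hit(query_len = 150L, subject_len = 90L,
                                     align_len = 45L, positives = 40L)),
               "bronze")
  expect_equal(classify_one(make_hit(query_len = 150L, subject_len = 200L,
                                     align_len = 40L, positives = 35L)),
               "unclassified")
  # coverage exactly 0.90 is gold ("at least 90%")
  expect_equal(classify_one(make_hit(query_len = 350L, subject_len = 120L,
                                     align_len = 108L, positives = 95L)),
               "gold")
  # no hit at all
  no_hit <- classify_tiers(make_put("P9", 500L), make_hit()[0, ])
  expect_equal(as.character(no_hit$tier), "unclassified")
})

test_that("weakening any single gold criterion demotes but never promotes", {
  gold <- make_hit(query_len = 400L, subject_len = 120L, align_len = 118L,
                   positives = 100L)
  degrade <- list(
    two_hsps = dplyr::mutate(gold, hsp_count = 2L),
    short_query = dplyr::mutate(gold, query_len = 299L, q_start = 1L,
                                q_end = 299L, align_len = 99L,
                                positives = 90L),
    small_subject = dplyr::mutate(gold, subject_len = 99L,
                                  align_len = 95L, positives = 80L),
    weak_positives = dplyr::mutate(gold, positives = 88L),  # 0.746
    low_coverage = dplyr::mutate(gold, align_len = 107L, positives = 90L)
  )
  for (nm in names(degrade)) {
    h <- degrade[[nm]]
    tier <- as.character(
      classify_tiers(make_put("P1", h$query_len), h)$tier)
    expect_false(tier == "gold", label = nm)
    expect_equal(tier, oracle_tier(h), label = nm)
  }
})

test_that("every gold hit also satisfies the silver thresholds", {
  sim <- default_sim()$sim
  ass <- classify_tiers(sim$puts, sim$hits)
  gold <- dplyr::filter(ass, tier == "gold")
  expect_true(all(gold$coverage >= 0.75))
  expect_true(all(gold$query_len >= 100))
})

test_that("classification is disjoint, complete, and matches a rule oracle", {
  sim <- default_sim()$sim
  ass <- classify_tiers(sim$puts, sim$hits)
  expect_equal(nrow(ass), nrow(sim$puts))
  expect_false(anyNA(ass$tier))
  counts <- tier_summary(ass)
  expect_equal(sum(counts$n), nrow(sim$puts))
  best <- best_hits(sim$hits)
  for (i in seq_len(nrow(ass))) {
    h <- best[best$put_id == ass$put_id[i], ]
    expect_equal(as.character(ass$tier[i]),
                 oracle_tier(if (nrow(h) == 1) h else NULL),
                 label = ass$put_id[i])
  }
})

test_that("tier_summary reports all levels and rejects duplicate PUTs", {
  ass <- tibble::tibble(
    put_id = paste0("P", 1:5),
    tier = c("gold", "silver", "silver", "bronze", "unclassified")
  )
  s <- tier_summary(ass)
  expect_equal(s$n, c(1L, 2L, 1L, 1L))
  expect_equal(tier_summary(ass[0, ])$n, rep(0L, 4))
  expect_error(tier_summary(dplyr::bind_rows(ass, ass[1, ])), "duplicate")
})

test_that("gold clipping and translation follow the declared rules", {
  put <- tibble::tibble(put_id = "P1", sequence = "AAATGGCCTAA",
                        length = 11L)
  hit <- make_hit(put_id = "P1", query_len = 11L, subject_len = 3L,
                  align_len = 3L, positives = 3L, q_start = 3L,
                  q_end = 11L, query_frame = 3L)
  ass <- tibble::tibble(put_id = "P1", tier = "gold",
                        subject_id = "gb|S1|", q_start = 3L, q_end = 11L,
                        query_frame = 3L)
  out <- trim_translate(put, ass)
  expect_equal(out$trimmed_cds, "ATGGCCTAA")
  expect_equal(out$protein, "MA*")

  # N-containing codons become X
  put2 <- tibble::tibble(put_id = "P2", sequence = "ATGNNA", length = 6L)
  ass2 <- tibble::tibble(put_id = "P2", tier = "gold",
                         subject_id = "gb|S1|", q_start = 1L, q_end = 6L,
                         query_frame = 1L)
  expect_equal(trim_translate(put2, ass2)$protein, "MX")

  # negative frame reverse-complements the clipped span
  put3 <- tibble::tibble(put_id = "P3", sequence = "TTACAT", length = 6L)
  ass3 <- tibble::tibble(put_id = "P3", tier = "gold",
                         subject_id = "gb|S1|", q_start = 1L, q_end = 6L,
                         query_frame = -1L)
  expect_equal(trim_translate(put3, ass3)$protein, "M*")

  # coordinates past the sequence end are a data inconsistency
  ass_bad <- dplyr::mutate(ass3, q_end = 9L)
  expect_error(trim_translate(put3, ass_bad), "past")
})

test_that("translated length is floor(clipped length / 3) across a fixture", {
  sim <- default_sim()$sim
  ass <- classify_tiers(sim$puts, sim$hits)
  prot <- trim_translate(sim$puts, ass)
  expect_gt(nrow(prot), 0)
  expect_equal(nchar(prot$protein), nchar(prot$trimmed_cds) %/% 3L)
  gold <- dplyr::filter(ass, tier == "gold")
  expect_equal(nchar(prot$trimmed_cds),
               gold$q_end[match(prot$put_id, gold$put_id)] -
                 gold$q_start[match(prot$put_id, gold$put_id)] + 1L)
})
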