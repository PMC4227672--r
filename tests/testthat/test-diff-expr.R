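test_that("pooling is count-weighted, identity for one sample", {
  a <- make_expr("G", 3L, 100L, "s1")
  b <- make_expr("G", 1L, 300L, "s2")
  pooled <- pool_samples(a, b)
  expect_equal(pooled$count, 4L)
  expect_equal(pooled$total_reads, 400L)
  expect_equal(pooled$normalized, 0.01)
  expect_equal(pool_samples(a)$normalized, a$normalized)
  zero <- pool_samples(make_expr("G", 0L, 100L, "s1"),
                       make_expr("G", 0L, 300L, "s2"))
  expect_equal(zero$count, 0L)
  expect_error(pool_samples(a, make_expr("H", 1L, 100L, "s2")),
               "universes")
})

test_that("fold differences put the larger abundance in the numerator", {
  a <- make_expr(c("g1", "g2", "g3", "g4"), c(1L, 0L, 5L, 0L),
                 113365193L, "n2")
  b <- make_expr(c("g1", "g2", "g3", "g4"), c(1L, 1L, 5L, 0L),
                 105109728L, "n4")
  cmp <- compare_expression(a, b, "n4_vs_n2")
  g1 <- cmp[cmp$gene_id == "g1", ]
  expect_equal(round(g1$fold_diff, 2), 1.08)
  expect_equal(g1$direction, "up")
  g2 <- cmp[cmp$gene_id == "g2", ]
  expect_true(g2$exclusive)
  expect_equal(g2$fold_diff, 0)      # the study's 0.00 sentinel
  expect_equal(g2$direction, "up")
  g4 <- cmp[cmp$gene_id == "g4", ]
  expect_false(g4$exclusive)
  expect_equal(g4$fold_diff, 1)
  expect_equal(g4$direction, "flat")
  # equal positive abundances are flat at fold 1
  eq <- compare_expression(make_expr("g", 2L, 100L),
                           make_expr("g", 2L, 100L), "c")
  expect_equal(eq$fold_diff, 1)
  expect_equal(eq$direction, "flat")
})

test_that("the printed top fold is recovered from printed abundances", {
  a <- tibble::tibble(gene_id = "tubulin", sample = "n2", count = 2L,
                      total_reads = 10L, normalized = 1.76e-8)
  b <- dplyr::mutate(a, sample = "n4", normalized = 1.95e-6)
  cmp <- compare_expression(a, b, "n4_vs_n2")
  # the study prints 110.55 from unrounded values; printed 3-digit
  # abundances reproduce it to ~1%
  expect_equal(cmp$fold_diff, 110.8, tolerance = 0.01)
  expect_equal(cmp$direction, "up")
})

test_that("swapping sides preserves folds and flips direction", {
  set.seed(90)
  a <- make_expr(sprintf("g%02d", 1:20), rpois(20, 5), 1000L, "a")
  b <- make_expr(sprintf("g%02d", 1:20), rpois(20, 5), 1200L, "b")
  ab <- compare_expression(a, b, "ab")
  ba <- compare_expression(b, a, "ba")
  keep <- !ab$exclusive
  expect_equal(ab$fold_diff[keep], ba$fold_diff[keep])
  flip <- c(up = "down", down = "up", flat = "flat")
  expect_equal(unname(flip[ab$direction[keep]]), ba$direction[keep])
  expect_true(all(ab$fold_diff[keep] >= 1))
})

test_that("the 20-fold call is inclusive and exclusives are flagged apart", {
  cmp <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    comparison = "c",
    abund_a = c(1e-8, 1e-8, 1e-8, 0),
    abund_b = c(110.6e-8, 19.9e-8, 21e-8, 1e-8),
    fold_diff = c(110.6, 19.9, 21, 0),
    direction = "up",
    exclusive = c(FALSE, FALSE, FALSE, TRUE)
  )
  hd <- highly_de(cmp, 20)
  expect_equal(hd$gene_id[!hd$exclusive], c("a", "c"))
  expect_equal(hd$gene_id[hd$exclusive], "d")
  expect_equal(nrow(highly_de(cmp[2, ], 20)), 0L)
})

test_that("reference scoring uses Euclidean distance from (1,1,1)", {
  mk <- function(genes, fa, fb) {
    tibble::tibble(gene_id = genes, comparison = "c", abund_a = fa,
                   abund_b = fb, fold_diff = pmax(fa, fb) / pmin(fa, fb),
                   direction = "flat", exclusive = FALSE)
  }
  cmp1 <- mk(c("g1", "g2", "g3"), c(1, 1, 1), c(1, 2, 3))
  cmp2 <- mk(c("g1", "g2", "g3"), c(1, 1, 1), c(1, 1, 2))
  cmp3 <- mk(c("g1", "g2", "g3"), c(1, 1, 1), c(1, 1, 2))
  scores <- select_reference(list(cmp1, cmp2, cmp3))
  expect_equal(scores$gene_id, c("g1", "g2", "g3"))
  expect_equal(scores$distance, c(0, 1, sqrt(6)))
  expect_error(select_reference(list(cmp1[0, ], cmp2[0, ], cmp3[0, ])),
               "no gene")
})

test_that("reference ranking ignores common rescaling of both sides", {
  set.seed(91)
  mk_pair <- function(k) {
    a <- make_expr(sprintf("g%02d", 1:15), rpois(15, 20) + 1L, 1000L, "a")
    b <- make_expr(sprintf("g%02d", 1:15), rpois(15, 20) + 1L, 1000L, "b")
    list(a = a, b = b)
  }
  pairs <- purrr::map(1:3, mk_pair)
  cmp <- purrr::map(pairs, ~ compare_expression(.x$a, .x$b, "c"))
  scaled <- purrr::map(pairs, function(p) {
    compare_expression(dplyr::mutate(p$a, normalized = normalized * 7),
                       dplyr::mutate(p$b, normalized = normalized * 7),
                       "c")
  })
  r1 <- select_reference(cmp)
  r2 <- select_reference(scaled)
  expect_equal(r1$gene_id, r2$gene_id)
  expect_equal(r1$distance, r2$distance)
  expect_equal(r1$distance == 0, r1$x == 1 & r1$y == 1 & r1$z == 1)
})
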