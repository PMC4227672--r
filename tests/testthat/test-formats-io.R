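test_that("FASTQ qualities decode at the configured Phred offset", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "!!!!"), fq)
  reads <- read_fastq(fq)
  expect_equal(reads$qualities[[1]], c(40L, 40L, 40L, 40L))
  expect_equal(reads$qualities[[2]], c(0L, 0L, 0L, 0L))
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  reads64 <- read_fastq(fq, phred_offset = 64)
  expect_equal(reads64$qualities[[1]], rep(9L, 4))
})

test_that("malformed FASTQ records raise errors naming the record", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@bad1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "bad1")
  writeLines(c("@bad2", "ACXT", "+", "IIII"), fq)
  expect_error(read_fastq(fq), "bad2")
  writeLines(character(0), fq)
  expect_equal(nrow(read_fastq(fq)), 0L)
})

test_that("FASTQ writing round-trips well-formed input byte for byte", {
  set.seed(11)
  reads <- random_reads(40)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1)
  write_fastq(read_fastq(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_fastq(f1), reads)
})

test_that("BLAST tabular rows map onto hit records and invalid rows fail", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  row <- paste("P1", "gb|S1|", "some protein", 350, 120, 1, 118, 100,
               84.7, 210.5, 1e-40, 3, 340, 2, sep = "\t")
  writeLines(c("# qseqid\tsseqid\t...", row), tab)
  hits <- read_blast_tab(tab)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$query_len, 350L)
  expect_equal(hits$subject_len, 120L)
  expect_equal(hits$hsp_count, 1L)
  expect_equal(hits$query_frame, 2L)

  bad <- sub("\t3\t340\t", "\t400\t420\t", row)  # q_start > query_len
  writeLines(bad, tab)
  expect_error(read_blast_tab(tab), "q_start")

  writeLines(character(0), tab)
  expect_equal(nrow(read_blast_tab(tab)), 0L)
})

test_that("PSL ingest converts coordinates and scores as declared", {
  psl <- withr::local_tempfile(fileext = ".psl")
  l1 <- paste(c(100, 0, 0, 0, 0, 0, 0, 0, "+", "r1", 100, 0, 100, "P1",
                1000, 0, 100, 1, "100,", "0,", "0,"), collapse = "\t")
  l2 <- paste(c(90, 5, 0, 1, 0, 0, 0, 0, "+", "r2", 100, 0, 96, "P2",
                1000, 0, 96, 1, "96,", "0,", "0,"), collapse = "\t")
  writeLines(c(l1, l2), psl)
  aln <- read_psl(psl)
  expect_equal(aln$aligned_len, c(100L, 96L))
  expect_equal(aln$score, c(100, 85))

  writeLines(paste(rep("1", 15), collapse = "\t"), psl)
  expect_error(read_psl(psl), "21")

  bad <- paste(c(90, 0, 0, 0, 0, 0, 0, 0, "+", "r1", 100, 90, 10, "P1",
                 1000, 0, 90, 1, "90,", "0,", "0,"), collapse = "\t")
  writeLines(bad, psl)
  expect_error(read_psl(psl), "qEnd")
})

test_that("PSL header blocks are skipped", {
  psl <- withr::local_tempfile(fileext = ".psl")
  hdr <- c("psLayout version 3", "",
           "match\tmis-\trep.", "     \tmatch\tmatch",
           "---------------------------------")
  l1 <- paste(c(100, 0, 0, 0, 0, 0, 0, 0, "+", "r1", 100, 0, 100, "P1",
                1000, 0, 100, 1, "100,", "0,", "0,"), collapse = "\t")
  writeLines(c(hdr, l1), psl)
  expect_equal(nrow(read_psl(psl)), 1L)
})

test_that("scientific rendering matches the study's table style", {
  expect_equal(render_sci(1.7638e-8), "1.76E-08")
  expect_equal(render_sci(0), "0.00E+00")
  set.seed(5)
  v <- 10^runif(200, -10, 3)
  parsed <- as.numeric(render_sci(v))
  expect_true(all(abs(parsed - v) / v < 5e-3))
})

test_that("write_table emits headers, scientific floats, and empty sets", {
  out <- withr::local_tempfile(fileext = ".tsv")
  write_table(make_expr("G1", 1L, 113365193L), out)
  lines <- readLines(out)
  expect_match(lines[1], "gene_id\tsample")
  expect_match(lines[2], "8\\.82E-09")
  write_table(make_expr(character(0), integer(0), integer(0)), out)
  expect_length(readLines(out), 1L)
})

test_that("Ct tables validate replicate density and positivity", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,gene,biorep,techrep,ct",
               "egg,g1,1,1,25", "egg,g1,1,2,25.2", "egg,g1,2,1,24.9"),
             csv)
  ct <- read_ct_table(csv)
  expect_equal(nrow(ct), 3L)
  writeLines(c("sample,gene,biorep,techrep,ct", "egg,g1,2,1,25"), csv)
  expect_error(read_ct_table(csv), "dense")
  writeLines(c("sample,gene,biorep,techrep,ct", "egg,g1,1,1,-1"), csv)
  expect_error(read_ct_table(csv), "positive")
})

test_that("mapping tables load term lists and reject duplicates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("nr_id\tuniprot_acc\tgo_mf\tgo_other\tpfam\tkegg",
               "gb|A1|\tQ00001\tGO:0003824;GO:0005515\t\tPF00001\tK00001",
               "gb|B1|\t\t\t\t\t"), tsv)
  m <- read_mapping_table(tsv)
  expect_equal(m$go_mf[[1]], c("GO:0003824", "GO:0005515"))
  expect_true(is.na(m$uniprot_acc[2]))
  expect_equal(m$pfam[[2]], character(0))
  writeLines(c("nr_id\tuniprot_acc\tgo_mf\tgo_other\tpfam\tkegg",
               "gb|A1|\tQ1\t\t\t\t", "gb|A1|\tQ2\t\t\t\t"), tsv)
  expect_error(read_mapping_table(tsv), "duplicate")
})
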