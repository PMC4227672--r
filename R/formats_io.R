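#' Read a 4-line FASTQ file into a read tibble
#'
#' Parses single-end FASTQ (strict 4-line records, optionally gzipped) into
#' the tidy read representation used throughout the package: one row per
#' read, with the Phred quality string decoded to an integer vector.
#'
#' @param path Path to a FASTQ file (`.gz` accepted).
#' @param phred_offset ASCII offset of the quality encoding. 33 is the
#'   Sanger / Illumina 1.8+ convention; 64 selects the legacy Illumina
#'   encoding used by some older instruments.
#' @return A tibble with columns `read_id` (character), `sequence`
#'   (character, alphabet `A,C,G,T,N`) and `qualities` (list of integer
#'   vectors, one Phred score per base).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)$qualities[[1]]
#' @export
read_fastq <- function(path, phred_offset = 33) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(), sequence = character(), qualities = list()
    ))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file ", path, " does not contain complete 4-line records (",
         length(lines), " lines)", call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  heads <- lines[idx]
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad_head <- !startsWith(heads, "@")
  if (any(bad_head)) {
    stop("FASTQ record ", which(bad_head)[1L], " in ", path,
         " does not start with '@': ", heads[which(bad_head)[1L]],
         call. = FALSE)
  }
  ids <- sub("^@", "", sub("\\s.*$", "", heads))
  len_mismatch <- nchar(seqs) != nchar(quals)
  if (any(len_mismatch)) {
    i <- which(len_mismatch)[1L]
    stop("FASTQ record '", ids[i], "': sequence length ", nchar(seqs[i]),
         " != quality length ", nchar(quals[i]), call. = FALSE)
  }
  bad_sym <- grepl("[^ACGTN]", seqs)
  if (any(bad_sym)) {
    i <- which(bad_sym)[1L]
    stop("FASTQ record '", ids[i], "': sequence contains symbols outside ",
         "{A,C,G,T,N}", call. = FALSE)
  }
  q <- lapply(quals, function(s) {
    if (nchar(s) == 0L) integer(0) else utf8ToInt(s) - as.integer(phred_offset)
  })
  neg <- vapply(q, function(v) length(v) > 0L && min(v) < 0L, logical(1))
  if (any(neg)) {
    i <- which(neg)[1L]
    stop("FASTQ record '", ids[i], "': negative Phred score after decoding ",
         "with offset ", phred_offset, call. = FALSE)
  }
  tibble::tibble(read_id = ids, sequence = seqs, qualities = q)
}

#' Write a read tibble back to 4-line FASTQ
#'
#' Inverse of [read_fastq()]: `write_fastq(read_fastq(x))` reproduces a
#' well-formed input byte for byte.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `qualities`).
#' @param path Output path.
#' @param phred_offset Quality encoding offset (default 33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, phred_offset = 33) {
  stopifnot(all(c("read_id", "sequence", "qualities") %in% names(reads)))
  qual_str <- vapply(reads$qualities, function(v) {
    if (length(v) == 0L) "" else intToUtf8(v + as.integer(phred_offset))
  }, character(1))
  out <- character(4L * nrow(reads))
  if (nrow(reads) > 0L) {
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$read_id)
    out[seq(2L, length(out), 4L)] <- reads$sequence
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qual_str
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Read assembled transcripts (PUTs) from FASTA
#'
#' @param path FASTA file of putatively unique transcripts.
#' @return Tibble with `put_id`, `sequence`, `length`. `put_id` must be
#'   unique within the file.
#' @export
read_puts <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate put_id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  tibble::tibble(
    put_id = ids,
    sequence = as.character(set),
    length = Biostrings::width(set)
  )
}

#' Write a PUT tibble to FASTA
#'
#' @param puts Tibble with `put_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_puts <- function(puts, path) {
  set <- Biostrings::DNAStringSet(puts$sequence)
  names(set) <- puts$put_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Fixed column contract for the BLAST tabular dialect consumed by the
# tiering stage. The order is part of the file format, not configurable.
blast_tab_cols <- c(
  "qseqid", "sseqid", "stitle", "qlen", "slen", "num_hsps", "length",
  "positive", "pident", "bitscore", "evalue", "qstart", "qend", "qframe"
)

#' Read protein-homology hits in the package's BLAST tabular dialect
#'
#' The dialect is a fixed 14-column tab-separated layout:
#' `qseqid, sseqid, stitle, qlen, slen, num_hsps, length, positive, pident,
#' bitscore, evalue, qstart, qend, qframe`, where `length` and `positive`
#' describe the best HSP. A `#`-prefixed header line is permitted and
#' skipped. Rows for the same query are preserved in file order.
#'
#' @param path Tab-separated hit file.
#' @return Tibble with one row per hit: `put_id`, `subject_id`,
#'   `subject_desc`, `query_len`, `subject_len`, `hsp_count`, `align_len`,
#'   `positives`, `identity_pct`, `bit_score`, `e_value`, `q_start`,
#'   `q_end`, `query_frame`.
#' @export
read_blast_tab <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = blast_tab_cols, comment = "#", na = character(),
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", stitle = "c",
      qlen = "d", slen = "d", num_hsps = "d", length = "d", positive = "d",
      pident = "d", bitscore = "d", evalue = "d",
      qstart = "d", qend = "d", qframe = "d"
    ),
    progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop("malformed BLAST tabular row at line ", probs$row[1L], " of ", path,
         ": expected ", probs$expected[1L], ", got '", probs$actual[1L], "'",
         call. = FALSE)
  }
  hits <- tibble::tibble(
    put_id = raw$qseqid, subject_id = raw$sseqid, subject_desc = raw$stitle,
    query_len = as.integer(raw$qlen), subject_len = as.integer(raw$slen),
    hsp_count = as.integer(raw$num_hsps), align_len = as.integer(raw$length),
    positives = as.integer(raw$positive), identity_pct = raw$pident,
    bit_score = raw$bitscore, e_value = raw$evalue,
    q_start = as.integer(raw$qstart), q_end = as.integer(raw$qend),
    query_frame = as.integer(raw$qframe)
  )
  validate_hits(hits, path)
  hits
}

validate_hits <- function(hits, origin = "hits") {
  bad <- which(
    hits$q_start < 1L | hits$q_start > hits$q_end |
      hits$q_end > hits$query_len
  )
  if (length(bad) > 0L) {
    i <- bad[1L]
    stop("hit for '", hits$put_id[i], "' in ", origin,
         ": query coordinates ", hits$q_start[i], "..", hits$q_end[i],
         " violate 1 <= q_start <= q_end <= query_len (",
         hits$query_len[i], ")", call. = FALSE)
  }
  bad <- which(hits$positives < 0L | hits$positives > hits$align_len)
  if (length(bad) > 0L) {
    stop("hit for '", hits$put_id[bad[1L]], "' in ", origin,
         ": positives outside [0, align_len]", call. = FALSE)
  }
  bad <- which(hits$subject_len < 1L | hits$hsp_count < 1L |
                 hits$e_value < 0)
  if (length(bad) > 0L) {
    stop("hit for '", hits$put_id[bad[1L]], "' in ", origin,
         ": subject_len and hsp_count must be >= 1, e_value >= 0",
         call. = FALSE)
  }
  invisible(hits)
}

#' Read read-to-transcript alignments from PSL
#'
#' Standard 21-column whitespace-separated PSL as produced by BLAT; the
#' optional 5-line textual header is detected and skipped. Coordinates are
#' 0-based half-open in the file and converted on ingest: `aligned_len` is
#' `qEnd - qStart` and the alignment score used for ranking is
#' `matches - mismatches`.
#'
#' @param path PSL file.
#' @return Tibble with `read_id`, `put_id`, `matches`, `mismatches`,
#'   `read_len`, `aligned_len`, `score`.
#' @export
read_psl <- function(path) {
  lines <- readr::read_lines(path)
  # BLAT's optional header: "psLayout version 3", blank/label lines, then a
  # dash ruler. Skip up to the ruler when present.
  if (length(lines) > 0L && grepl("^psLayout", lines[1L])) {
    ruler <- grep("^-+$", lines)
    if (length(ruler) == 0L) {
      stop("PSL header in ", path, " has no closing ruler line",
           call. = FALSE)
    }
    lines <- lines[-seq_len(ruler[1L])]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(), put_id = character(), matches = integer(),
      mismatches = integer(), read_len = integer(), aligned_len = integer(),
      score = double()
    ))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 21L)) {
    stop("PSL line ", which(nf < 21L)[1L], " of ", path, " has ",
         nf[nf < 21L][1L], " columns; 21 required", call. = FALSE)
  }
  get_num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), k)))
    if (anyNA(v)) {
      stop("PSL line ", which(is.na(v))[1L], " of ", path,
           ": non-numeric value in column ", k, call. = FALSE)
    }
    v
  }
  get_chr <- function(k) vapply(fields, `[[`, character(1), k)
  matches <- get_num(1L)
  mismatches <- get_num(2L)
  read_len <- get_num(11L)
  q_start0 <- get_num(12L)
  q_end0 <- get_num(13L)
  if (any(q_end0 < q_start0)) {
    stop("PSL line ", which(q_end0 < q_start0)[1L], " of ", path,
         ": qEnd < qStart", call. = FALSE)
  }
  aln <- tibble::tibble(
    read_id = get_chr(10L),
    put_id = get_chr(14L),
    matches = as.integer(matches),
    mismatches = as.integer(mismatches),
    read_len = as.integer(read_len),
    aligned_len = as.integer(q_end0 - q_start0),
    score = matches - mismatches
  )
  bad <- which(aln$matches + aln$mismatches > aln$aligned_len |
                 aln$aligned_len > aln$read_len)
  if (length(bad) > 0L) {
    stop("PSL line ", bad[1L], " of ", path,
         ": matches + mismatches <= aligned_len <= read_len violated",
         call. = FALSE)
  }
  aln
}

#' Read the offline NR-to-UniProt mapping table
#'
#' Tab-separated with header `nr_id, uniprot_acc, go_mf, go_other, pfam,
#' kegg`; term columns are semicolon-separated lists and may be empty. An
#' empty `uniprot_acc` marks an unmapped NR identifier.
#'
#' @param path Mapping TSV.
#' @return Tibble with `nr_id`, `uniprot_acc` (`NA` when unmapped) and
#'   list-columns `go_mf`, `go_other`, `pfam`, `kegg`.
#' @export
read_mapping_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  need <- c("nr_id", "uniprot_acc", "go_mf", "go_other", "pfam", "kegg")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("mapping table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$nr_id)) {
    stop("mapping table ", path, " has duplicate nr_id: ",
         raw$nr_id[duplicated(raw$nr_id)][1L], call. = FALSE)
  }
  split_terms <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, ";", fixed = TRUE)[[1L]]
    })
  }
  tibble::tibble(
    nr_id = raw$nr_id,
    uniprot_acc = ifelse(nzchar(raw$uniprot_acc), raw$uniprot_acc,
                         NA_character_),
    go_mf = split_terms(raw$go_mf),
    go_other = split_terms(raw$go_other),
    pfam = split_terms(raw$pfam),
    kegg = split_terms(raw$kegg)
  )
}

#' Read a qRT-PCR Ct table
#'
#' CSV with header `sample,gene,biorep,techrep,ct`. Replicate indices must
#' be dense from 1 within each sample x gene combination.
#'
#' @param path CSV of Ct values.
#' @return Tibble with `sample`, `gene`, `biological_rep`, `technical_rep`,
#'   `ct`.
#' @export
read_ct_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample = "c", gene = "c", biorep = "i", techrep = "i", ct = "d"
  ), progress = FALSE, show_col_types = FALSE)
  if (any(raw$ct <= 0)) {
    stop("Ct table ", path, " contains non-positive Ct values",
         call. = FALSE)
  }
  ct <- tibble::tibble(
    sample = raw$sample, gene = raw$gene,
    biological_rep = raw$biorep, technical_rep = raw$techrep, ct = raw$ct
  )
  dense <- ct |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(
      ok = setequal(unique(.data$biological_rep),
                    seq_len(max(.data$biological_rep))),
      .groups = "drop"
    )
  if (!all(dense$ok)) {
    bad <- dense[!dense$ok, ][1L, ]
    stop("Ct table ", path, ": biological replicate indices for ",
         bad$sample, "/", bad$gene, " are not dense from 1", call. = FALSE)
  }
  ct
}

#' Render numbers in the package's table style
#'
#' Scientific notation with 3 significant digits and an upper-case
#' exponent, e.g. `1.76E-08`; zero renders as `0.00E+00`. `parse` with
#' `as.numeric()` recovers the value to 3 significant digits.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @examples
#' render_sci(c(1.7638e-8, 0))
#' @export
render_sci <- function(x) {
  out <- sprintf("%.2E", x)
  out[x == 0] <- "0.00E+00"
  out
}

#' Write a tabular result as TSV
#'
#' Writes any result tibble as a tab-separated file with a header line.
#' Double columns are rendered in scientific notation with 3 significant
#' digits (`1.76E-08` style) to match the study's table conventions;
#' integers and text pass through unchanged.
#'
#' @param records A data frame sharing one schema.
#' @param path Output path.
#' @param sci Logical: render doubles in scientific notation (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sci = TRUE) {
  out <- as.data.frame(records)
  if (sci) {
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- render_sci(out[[j]])
    }
  }
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
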