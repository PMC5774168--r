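test_that("FASTA reading folds case, joins wrapped lines and parses headers", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "acgt", "ACGT"), fa)
  x <- read_fasta(fa, "nt")
  expect_equal(x$id, "t1")
  expect_equal(x$seq, "ACGTACGT")

  writeLines(c(">a x", "AA", ">b", "CC"), fa)
  y <- read_fasta(fa, "nt")
  expect_equal(y$id, c("a", "b"))
  expect_equal(y$description, c("x", ""))
})

test_that("FASTA reading rejects duplicates and illegal characters", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AA", ">a", "CC"), fa)
  expect_error(read_fasta(fa, "nt"), "duplicate.*a")

  writeLines(c(">a", "ACGU"), fa)
  expect_error(read_fasta(fa, "nt"), "position 4")

  file.create(fa2 <- withr::local_tempfile(fileext = ".fa"))
  expect_warning(z <- read_fasta(fa2, "nt"), "no FASTA records")
  expect_equal(nrow(z), 0)
})

test_that("FASTA write/read round-trips ids, descriptions and sequences", {
  x <- tibble::tibble(id = c("t1", "t2"), description = c("a note", ""),
                      seq = c(strrep("ACGT", 40), "GGCCTTAA"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, fa, width = 50)
  expect_equal(read_fasta(fa, "nt"), x)
})

test_that("FASTQ qualities decode from Phred+33", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "!!!!"), fq)
  x <- read_fastq(fq)
  expect_equal(x$qual[[1]], rep(40L, 4))
  expect_equal(x$qual[[2]], rep(0L, 4))
})

test_that("FASTQ structural defects are errors", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "length mismatch.*r1")

  writeLines(c("@r1", "ACGT", "+"), fq)
  expect_error(read_fastq(fq), "truncated")
})

test_that("read filtering applies length, ambiguity and mean-error rules", {
  mk <- function(id, seq, q) tibble::tibble(id = id, seq = seq,
                                            qual = list(q))
  reads <- dplyr::bind_rows(
    mk("len39", strrep("A", 39), rep(40L, 39)),   # below 40 bases
    mk("len40", strrep("A", 40), rep(40L, 40)),
    mk("hasN", paste0(strrep("A", 25), "N", strrep("A", 24)), rep(40L, 50)),
    mk("q20", strrep("A", 50), rep(20L, 50)),     # mean error exactly 0.01
    mk("q19", strrep("A", 50), rep(19L, 50)),     # mean error 10^-1.9
    mk("short_and_N", paste0("N", strrep("A", 10)), rep(40L, 11))
  )
  out <- filter_reads(reads)
  expect_equal(out$reads$id, c("len40", "q20"))
  # first-failing-rule attribution: the 11-base read with an N counts as
  # a length discard, not an ambiguity discard
  expect_equal(out$discards$n, c(2L, 1L, 1L))
  expect_equal(nrow(out$reads) + sum(out$discards$n), nrow(reads))
  # idempotence
  again <- filter_reads(out$reads)
  expect_equal(again$reads, out$reads)
  expect_equal(sum(again$discards$n), 0L)
})

test_that("contig filtering keeps >= 150 nt and preserves order", {
  contigs <- tibble::tibble(
    id = c("a", "b", "c"), description = "",
    seq = vapply(c(149, 150, 151), function(n) strrep("A", n), character(1)))
  kept <- filter_contigs(contigs)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(filter_contigs(kept), kept)
  empty <- contigs[0, ]
  expect_equal(nrow(filter_contigs(empty)), 0)
})

test_that("hit tables parse the tabular dialect and reject malformed rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "t1\tP1\t98.00\t100\t2\t0\t1\t300\t1\t100\t1e-50\t200"), tf)
  h <- read_hit_table(tf)
  expect_equal(h$query_id, "t1")
  expect_equal(h$identity, 0.98)
  expect_equal(c(h$s_start, h$s_end), c(1L, 100L))
  expect_equal(h$q_nongap, 300L)
  expect_true(is.na(h$frame))

  writeLines("t1\tP1\t98.00\t100\t2\t0\t1\t300\t1\t100\t1e-50", tf)
  expect_error(read_hit_table(tf), "12 or 13.*11.*line 1")
  writeLines("t1\tP1\tninety\t100\t2\t0\t1\t300\t1\t100\t1e-50\t200", tf)
  expect_error(read_hit_table(tf), "unparsable")
})

test_that("hit tables round-trip through write_hit_table", {
  ref <- tiny_reference()
  tx <- tibble::tibble(id = "t1", description = "",
                       seq = substr(ref$cds[1], 1, 240))
  hits <- translated_search(tx, ref$proteome)
  expect_gt(nrow(hits), 0)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, tf)
  back <- read_hit_table(tf)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$subject_id, hits$subject_id)
  expect_equal(back$frame, hits$frame)
  for (col in c("q_aa_start", "q_aa_end", "s_start", "s_end", "aln_len",
                "mismatches", "gap_opens", "q_nongap"))
    expect_equal(back[[col]], hits[[col]], info = col)
  expect_equal(back$identity, hits$identity, tolerance = 1e-3)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-3)
  expect_equal(back$e_value, hits$e_value, tolerance = 1e-4)
})
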