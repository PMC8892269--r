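test_that("read_fasta normalizes case and RNA alphabet and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  s <- read_fasta(f)
  expect_equal(names(s), "a")
  expect_equal(as.character(s[[1]]), "ACGT")

  writeLines(c(">a", "ac", "gu"), f)
  expect_equal(as.character(read_fasta(f)[[1]]), "ACGT")

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate.*a")

  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("minus-strand two-exon transcript assembles the reverse complement", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".gff3")
  m <- read_transcript_models(write_toy_gff3(f), g)
  # hand-derived: exons chr1:13-20 then chr1:1-8 in transcript order,
  # each reverse-complemented
  chr <- as.character(g[[1]])
  expected <- paste0(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chr, 13, 20)))),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chr, 1, 8))))
  )
  expect_equal(m$sequence, expected)
  expect_equal(nchar(m$sequence), 16L)
  # transcript order: minus strand lists the 3'-most genomic exon first
  expect_equal(m$exons[[1]]$start, c(13L, 1L))
})

test_that("single-exon plus-strand CDS covering the whole exon maps to 1..length", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAA"))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1\t9\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t9\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttoy\texon\t1\t9\t.\t+\t.\tParent=t1",
    "chr1\ttoy\tCDS\t1\t9\t.\t+\t0\tParent=t1"
  ), f)
  m <- read_transcript_models(f, g)
  expect_equal(m$cds_start, 1L)
  expect_equal(m$cds_end, 9L)
  expect_true(m$cds_ok)
  expect_equal(m$sequence, "ATGAAATAA")
})

test_that("BED12 and GFF3 encodings of the same model agree", {
  g <- toy_genome()
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".bed")
  m1 <- read_transcript_models(write_equiv_gff3(f1), g)
  m2 <- read_transcript_models(write_equiv_bed12(f2), g)
  for (col in c("transcript_id", "chrom", "strand", "cds_start", "cds_end",
                "cds_ok", "sequence")) {
    expect_equal(m1[[col]], m2[[col]], info = col)
  }
  expect_equal(m1$exons[[1]], m2$exons[[1]])
  expect_equal(m1$cds_end - m1$cds_start + 1L, 12L)
})

test_that("malformed CDS is flagged non-qualifying and unknown chromosomes error", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t1\t20\t.\t+\t.\tID=tbad",
    "chr1\ttoy\texon\t1\t20\t.\t+\t.\tParent=tbad",
    "chr1\ttoy\tCDS\t1\t8\t.\t+\t0\tParent=tbad"
  ), f)
  expect_warning(m <- read_transcript_models(f, g), "divisible by 3")
  expect_false(m$cds_ok)

  writeLines(c(
    "##gff-version 3",
    "chrX\ttoy\tmRNA\t1\t20\t.\t+\t.\tID=t2",
    "chrX\ttoy\texon\t1\t20\t.\t+\t.\tParent=t2"
  ), f)
  expect_error(read_transcript_models(f, g), "unknown chromosome")
})

test_that("SAM subset reading applies flags, CIGAR spans and multimap policy", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t100\t255\t28M\t*\t0\t0\t*\t*",
    "r2\t0\tchr1\t200\t255\t3S21M\t*\t0\t0\t*\t*\tNH:i:2",
    "r2\t256\tchr1\t300\t255\t21M\t*\t0\t0\t*\t*\tNH:i:2",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r4\t16\tchr1\t400\t255\t10M5N10M\t*\t0\t0\t*\t*"
  ), f)
  reads <- read_alignments(f, kind = "sam")
  expect_equal(nrow(reads), 4L)              # unmapped r3 skipped
  expect_equal(reads$weight[reads$read_id == "r1"], 1)
  expect_equal(reads$weight[reads$read_id == "r2"], c(0.5, 0.5))
  expect_equal(reads$length[reads$read_id == "r2"], c(21L, 21L))
  expect_equal(reads$length[reads$read_id == "r4"], 25L)  # M+N+M span
  expect_equal(reads$strand[reads$read_id == "r4"], "-")
  # weights of one physical read sum to 1
  sums <- tapply(reads$weight, reads$read_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  primary <- read_alignments(f, kind = "sam", multimap = "primary")
  expect_equal(nrow(primary), 3L)
  expect_true(all(primary$weight == 1))

  writeLines(c("@SQ\tSN:chr1\tLN:1000",
               "r1\t0\tchr2\t1\t255\t20M\t*\t0\t0\t*\t*"), f)
  expect_error(read_alignments(f, kind = "sam"), "absent from SAM header")
})

test_that("tabular alignments round-trip through write_alignments", {
  reads <- make_reads("tx", c(5L, 50L, 50L), length = c(21L, 22L, 22L),
                      strand = c("+", "-", "+"), weight = c(1, 0.5, 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(reads, f)
  back <- read_alignments(f, kind = "tabular")
  expect_equal(as.data.frame(back), as.data.frame(reads))
  # the on-disk start column is 0-based
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(tab$start, reads$start - 1L)
})

test_that("bedGraph writing merges runs, drops zeros and round-trips", {
  # values at 0-based offset 10, i.e. 1-based start 11
  tr <- coverage_track(c(0, 0, 3, 3, 1), "ref", start = 11L)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  lines <- readLines(f)
  expect_equal(lines[-1], c("ref\t12\t14\t3", "ref\t14\t15\t1"))

  empty <- coverage_track(rep(0, 5), "ref", start = 11L)
  write_bedgraph(empty, f)
  expect_equal(length(readLines(f)), 1L)     # header only

  set.seed(42)
  v <- sample(0:5, 50, replace = TRUE)
  write_bedgraph(coverage_track(v, "chr9", start = 101L), f)
  back <- read_bedgraph(f, span = c(101L, 150L))
  expect_equal(back$values, as.numeric(v))
})

test_that("synthetic models and alignments round-trip through the readers", {
  cfg <- sim_config(seed = 3, n_rfp = 500L)
  loc <- make_synthetic_locus(cfg)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(loc$models, gff)
  back <- read_transcript_models(gff, loc$genome)
  back <- back[match(loc$models$transcript_id, back$transcript_id), ]
  expect_equal(back$sequence, loc$models$sequence)
  expect_equal(back$cds_start, loc$models$cds_start)
  expect_equal(back$cds_end, loc$models$cds_end)
  expect_equal(back$exons, loc$models$exons)

  rfp <- simulate_rfp(cfg, loc$models)
  aln <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(rfp, aln)
  back_reads <- read_alignments(aln, kind = "tabular")
  canonical <- c("read_id", "ref", "start", "length", "strand", "weight")
  expect_equal(as.data.frame(back_reads[canonical]),
               as.data.frame(rfp[canonical]))
})
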