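test_that("FASTA reading normalizes case and validates the alphabet", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", "ACGT", ">chr2 description", "acgtacgt"), p)
  g <- read_genome_fasta(p)
  expect_equal(unname(chrom_lengths(g)), c(8L, 8L))
  expect_named(chrom_lengths(g), c("chr1", "chr2"))
  expect_equal(subsequence(g, "chr2", 0, 4), "ACGT")  # uppercased

  writeLines(c(">chr1", "ACXT"), p)
  expect_error(read_genome_fasta(p), "non-ACGTN")
})

test_that("subsequence respects 0-based half-open bounds", {
  g <- genome_from_strings(c(chrA = "ACGTACGTAC"))
  expect_equal(nchar(subsequence(g, "chrA", 2, 7)), 5L)
  expect_equal(subsequence(g, "chrA", 0, 2), "AC")
  expect_error(subsequence(g, "chrA", 5, 11), "outside")
  expect_error(subsequence(g, "chrB", 0, 1), "unknown chromosome")
})

test_that("BED and bedGraph dialects parse coordinates and scores", {
  p <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", p)
  tr <- read_bed(p)
  expect_equal(tr$df$end - tr$df$start, 10L)

  writeLines("chr1\t0\t5\t0.8", p)
  bg <- read_bed(p, dialect = "bedgraph")
  expect_equal(bg$df$score, 0.8)

  writeLines(c("chr1\t5\t9\tx\t3", "chr1\t20\t10"), p)
  expect_error(read_bed(p), "line 2")
})

test_that("interval overlap queries agree with a brute-force scan", {
  set.seed(7)
  for (rep_i in 1:5) {
    n <- sample(20:200, 1)
    df <- data.frame(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(0:900, n, replace = TRUE))
    df$end <- df$start + sample(1:120, n, replace = TRUE)
    tr <- interval_track(df)
    for (q in 1:20) {
      qs <- sample(0:950, 1); qe <- qs + sample(1:150, 1)
      chrom <- sample(c("c1", "c2", "c3"), 1)
      got <- track_overlaps(tr, chrom, qs, qe)
      want <- oracle_overlaps(df, chrom, qs, qe)
      expect_equal(got$start, want$start)
      expect_equal(got$overlap_bp, want$overlap_bp)
    }
  }
})

test_that("PFM library parsing normalizes counts with pseudocount", {
  p <- tempfile(fileext = ".pfm")
  writeLines(c(">M1", "A [ 10 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]",
               ">M2", "A 1 2", "C 3 4", "G 5 6", "T 7 8"), p)
  lib <- read_pfm_library(p, pseudocount = 0.01)
  expect_length(lib, 2)
  expect_equal(unname(lib[[1]]$mat["A", 1]), 10.01 / 10.04)
  expect_equal(colSums(lib[[2]]$mat), c(1, 1), ignore_attr = TRUE)

  empty <- tempfile()
  file.create(empty)
  expect_warning(res <- read_pfm_library(empty), "empty")
  expect_length(res, 0)

  # all-zero column without pseudocount is rejected
  writeLines(c(">Z", "A 0", "C 0", "G 0", "T 0"), p)
  expect_error(read_pfm_library(p, pseudocount = 0), "all zeros")
})

test_that("PFM round trip through JASPAR text preserves frequencies", {
  counts <- matrix(c(10, 2, 3, 5, 0, 8, 1, 11), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- tempfile()
  write_pfm_library(list(M = counts), p)
  lib <- read_pfm_library(p, pseudocount = 0)
  expect_equal(lib[[1]]$mat, sweep(counts, 2, colSums(counts), "/"))
})

test_that("feature matrix writers honour both dialects", {
  schema <- data.frame(class = c("a", "a", "b"),
                       name = c("f1", "f2", "g1"))
  mat <- matrix(c(0, 2.5, 0, 1.25, 0, -3), nrow = 2, byrow = TRUE)
  rownames(mat) <- c("i1", "i2")
  fm <- feature_matrix(mat, schema)
  expect_equal(colnames(fm), c("a.f1", "a.f2", "b.g1"))
  expect_equal(unname(class_widths(fm)), c(2L, 1L))

  p <- tempfile()
  write_feature_matrix(fm, labels = c(1, -1), p, dialect = "sparse")
  lines <- readLines(p)
  expect_equal(lines[1], "1 2:2.5")
  expect_equal(lines[2], "-1 1:1.25 3:-3")

  write_feature_matrix(fm, labels = c("methylated", "unmethylated"), p,
                       dialect = "tsv")
  back <- read_feature_matrix(p)
  expect_equal(unname(back$mat), unname(unclass(fm)[, ]))
  expect_equal(back$labels, c("methylated", "unmethylated"))

  expect_error(feature_matrix(matrix(c(1, NA), 1), schema[1:2, ]),
               "finite|length")
})

test_that("GTF-like annotation reading derives 0-based TSS per strand", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\tgene\t101\t500\t.\t+\t.\t",
           'gene_id "G1"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\tgene\t701\t900\t.\t-\t.\t",
           'gene_id "G2"; gene_biotype "lincRNA";'),
    paste0("chr1\tsrc\ttranscript\t101\t500\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "G1.T1"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\texon\t101\t220\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "G1.T1"; gene_biotype "protein_coding";')),
    p)
  ann <- read_gtf(p)
  expect_equal(ann$genes$df$start, c(100L, 700L))
  expect_equal(ann$genes$df$tss, c(100L, 899L))
  expect_equal(ann$genes$df$biotype, c("protein_coding", "lincRNA"))
  expect_equal(nrow(ann$exons$df), 1L)
  expect_equal(ann$exons$df$end - ann$exons$df$start, 120L)
})
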