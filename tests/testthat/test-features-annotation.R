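# a hand-built annotation bundle on one 1 Mb chromosome
toy_bundle <- function() {
  genes <- interval_track(data.frame(
    chrom = "chr1", start = c(6000L, 40000L), end = c(9000L, 42000L),
    strand = c("+", "-"), gene_id = c("G1", "G2"),
    biotype = c("protein_coding", "lincRNA"),
    tss = c(6000L, 41999L)), "genes")
  transcripts <- interval_track(data.frame(
    chrom = "chr1", start = c(6000L, 6000L, 6000L, 40000L),
    end = c(9000L, 8000L, 8500L, 42000L),
    gene_id = c("G1", "G1", "G1", "G2"),
    transcript_id = paste0("T", 1:4)), "transcripts")
  exons <- interval_track(data.frame(
    chrom = "chr1", start = c(6100L, 7000L), end = c(6220L, 7400L),
    gene_id = c("G1", "G1")), "exons")
  snps <- interval_track(data.frame(
    chrom = "chr1", start = c(5050L, 5600L, 20000L),
    end = c(5051L, 5601L, 20001L),
    name = c("T/C", "A/G", "T/C")), "snps")
  repeats <- interval_track(data.frame(
    chrom = "chr1", start = c(4800L, 5200L, 30000L),
    end = c(5100L, 5300L, 30350L),
    name = c("AluY", "L1", "AluSx")), "repeats")
  selfalign <- interval_track(data.frame(
    chrom = "chr1", start = 5100L, end = 5350L, name = "self"), "selfalign")
  annotation_bundle(genes, transcripts, exons, snps, repeats, selfalign)
}

toy_rec <- function() record_from_seq(strrep("ACGT", 125),
                                      island_start = 0L, island_end = 500L,
                                      win_start = 4750L, chrom = "chr1")
# island [4750, 5250), midpoint 5000

test_that("TSS distances are emitted in log and normalized form", {
  b <- toy_bundle()
  rec <- toy_rec()
  v <- tss_distance_features(rec, b$genes, chrom_len = 1e6)
  expect_equal(v[["log_any"]], log10(1 + 1000))       # TSS 6000, mid 5000
  expect_equal(v[["norm_any"]], 1000 / 1e6)
  expect_equal(v[["log_coding"]], log10(1001))        # G1 is coding
  # an island overlapping a TSS scores distance 0
  rec0 <- record_from_seq(strrep("A", 100), win_start = 5980L,
                          chrom = "chr1")
  v0 <- tss_distance_features(rec0, b$genes, 1e6)
  expect_equal(v0[["log_any"]], 0)
  expect_equal(v0[["norm_any"]], 0)
  # no protein-coding gene -> chromosome-length sentinel
  nc <- b$genes
  nc$df$biotype <- "lincRNA"
  v2 <- tss_distance_features(rec, interval_track(nc$df, "genes"), 1e6)
  expect_equal(v2[["norm_coding"]], 1)
})

test_that("genomic attributes count genes, exons and transcripts", {
  b <- toy_bundle()
  # island overlapping gene G1 with 3 transcripts and both exons
  rec <- record_from_seq(strrep("ACGT", 500), island_start = 0L,
                         island_end = 2000L, win_start = 6000L,
                         chrom = "chr1")
  v <- genomic_attribute_features(rec, b)
  expect_equal(v[["n_genes"]], 1)
  expect_equal(v[["gene_total_len"]], 3000)
  expect_equal(v[["n_exons"]], 2)
  expect_equal(v[["exon_total_len"]], 120 + 400)
  expect_equal(v[["exon_mean_len"]], 260)
  expect_equal(v[["n_transcripts"]], 3)
  expect_equal(v[["tx_per_gene"]], 3)
  expect_equal(v[["island_len"]], 2000)

  # island with no annotation at all
  far <- record_from_seq(strrep("ACGT", 25), win_start = 900000L,
                         chrom = "chr1")
  v0 <- genomic_attribute_features(far, b)
  expect_equal(unname(v0[1:8]), rep(0, 8))
  expect_equal(v0[["island_len"]], 100)
  expect_equal(v0[["cpg_pct"]], 2 * 25 / 100)
})

test_that("two genes with 3 and 1 transcripts give 4 transcripts, 2 per gene", {
  b <- toy_bundle()
  rec <- record_from_seq(strrep("A", 40000), island_start = 0L,
                         island_end = 40000L, win_start = 5000L,
                         chrom = "chr1")
  v <- genomic_attribute_features(rec, b)
  expect_equal(v[["n_genes"]], 2)
  expect_equal(v[["n_transcripts"]], 4)
  expect_equal(v[["tx_per_gene"]], 2)
})

test_that("repeat features clip overlaps per window and find nearest Alu-Y", {
  b <- toy_bundle()
  rec <- toy_rec()   # island [4750, 5250)
  v <- repeat_features(rec, b, chrom_len = 1e6)
  expect_length(v, 19L)
  # exact window: AluY [4800,5100) fully inside (300 bp), L1 [5200,5300)
  # clipped to 50 bp
  expect_equal(v[["exact_rep_count"]], 2)
  expect_equal(v[["exact_rep_bp"]], 300 + 50)
  expect_equal(v[["exact_rep_frac"]], 350 / 500)
  expect_equal(v[["exact_aluy_bp"]], 300)
  expect_equal(v[["exact_selfalign_frac"]], 150 / 500)
  # +/-400 window [4350, 5650): L1 fully inside
  expect_equal(v[["w400_rep_bp"]], 300 + 100)
  # nearest AluY contains the midpoint
  expect_equal(v[["aluy_nearest_dist"]], 0)

  empty <- annotation_bundle(b$genes, b$transcripts, b$exons, b$snps,
                             interval_track(data.frame(chrom = "chrZ",
                                                       start = 0L,
                                                       end = 1L,
                                                       name = "x")),
                             b$selfalign)
  v0 <- repeat_features(rec, empty, chrom_len = 1e6)
  expect_equal(unname(v0[grep("rep|aluy", names(v0))][1:10]),
               rep(0, 10))
  expect_equal(v0[["aluy_nearest_dist"]], 1e6)
})

test_that("repeat window aggregates match the brute-force clipping oracle", {
  set.seed(31)
  for (i in 1:5) {
    df <- data.frame(chrom = "c", start = sample(0:5000, 60))
    df$end <- df$start + sample(50:400, 60, replace = TRUE)
    df$name <- sample(c("AluY", "L1", "MIR"), 60, replace = TRUE)
    tr <- interval_track(df)
    qs <- sample(1000:3000, 1); qe <- qs + 500L
    got <- track_overlaps(tr, "c", qs, qe)
    want <- oracle_overlaps(df, "c", qs, qe)
    expect_equal(sum(got$overlap_bp), sum(want$overlap_bp))
    expect_equal(nrow(got), nrow(want))
  }
})

test_that("SNP features honour window membership and T/C restriction", {
  b <- toy_bundle()
  rec <- toy_rec()  # midpoint 5000
  v <- snp_features(rec, b$snps)
  expect_length(v, 8L)
  # T/C SNP at 5050 (50 bp), A/G at 5600 (outside +/-400 window end 5650?
  # island [4750,5250) +400 -> [4350,5650): both inside)
  expect_equal(v[["w400_all_count"]], 2)
  expect_equal(v[["w400_all_dist"]], 50)
  expect_equal(v[["w400_tc_count"]], 1)
  expect_equal(v[["w400_tc_dist"]], 50)
  expect_equal(v[["w900_all_count"]], 2)

  none <- interval_track(data.frame(chrom = "c9", start = 1L, end = 2L,
                                    name = "A/G"))
  v0 <- snp_features(rec, none)
  expect_equal(unname(v0), c(0, 400, 0, 400, 0, 900, 0, 900))
})

test_that("enlarging the window never decreases count features", {
  b <- toy_bundle()
  rec <- toy_rec()
  v <- repeat_features(rec, b, 1e6)
  expect_gte(v[["w400_rep_count"]], v[["exact_rep_count"]])
  expect_gte(v[["w900_rep_count"]], v[["w400_rep_count"]])
  s <- snp_features(rec, b$snps)
  expect_gte(s[["w900_all_count"]], s[["w400_all_count"]])
  expect_gte(s[["w900_tc_count"]], s[["w400_tc_count"]])
})
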