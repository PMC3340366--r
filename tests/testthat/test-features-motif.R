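uniform_pfm <- function(L = 4) {
  pfm(matrix(0.25, 4, L), name = "uniform", type = "frequency")
}

consensus_pfm <- function(motif, strength = 100) {
  L <- nchar(motif)
  counts <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(motif, "")[[1]], c("A", "C", "G", "T"))
  for (j in seq_len(L)) counts[idx[j], j] <- strength
  pfm(sweep(counts + 0.01, 2, colSums(counts) + 0.04, "/"),
      name = motif, type = "frequency")
}

test_that("uniform PFMs score zero everywhere; ratio PFMs of ones too", {
  m <- weight_score_model(uniform_pfm(), epsilon = 0, theta = 1)
  got <- weight_score_scan(m, "ACGTACGTA")
  expect_equal(got$max_score, 0)
  expect_equal(got$hit_count, 0)

  ones <- pfm(matrix(1, 4, 5), name = "ones", type = "ratio")
  m2 <- weight_score_model(ones, theta = 5)
  got2 <- weight_score_scan(m2, random_seq(50))
  expect_equal(got2$max_score, 0)
})

test_that("a consensus PFM scores ~ 4*log2(4) at its planted position", {
  m <- weight_score_model(consensus_pfm("CGCG"), epsilon = 0.01, theta = 5)
  got <- weight_score_scan(m, "ACGCGT")
  expect_lt(abs(got$max_score - 8), 0.15)
  expect_equal(which.max(got$scores), 2L)   # offset of "CGCG"
  expect_gte(got$hit_count, 1)
})

test_that("scanning equals per-position brute-force rescoring", {
  set.seed(17)
  for (i in 1:6) {
    L <- sample(4:20, 1)
    mat <- matrix(rnorm(4 * L), 4, L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    model <- structure(list(name = "r", w = mat, type = "ratio",
                            epsilon = 0.01, theta = 2),
                       class = "WeightScoreModel")
    s <- random_seq(sample(100:2000, 1))
    if (i %% 2 == 0) {   # inject Ns
      pos <- sample(nchar(s), 5)
      for (p in pos) substr(s, p, p) <- "N"
    }
    got <- weight_score_scan(model, s)
    want <- oracle_scan(mat, s)
    expect_equal(got$scores, want)
    ok <- !is.na(want)
    expect_equal(got$max_score, if (any(ok)) max(want[ok]) else 0)
    expect_equal(got$hit_count, sum(want[ok] >= 2))
  }
})

test_that("reverse-complementing the sequence leaves scan results unchanged", {
  set.seed(29)
  for (i in 1:5) {
    L <- sample(5:12, 1)
    mat <- matrix(rnorm(4 * L), 4, L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    model <- structure(list(name = "r", w = mat, type = "ratio",
                            epsilon = 0.01, theta = 1),
                       class = "WeightScoreModel")
    s <- random_seq(300)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    a <- weight_score_scan(model, s)
    b <- weight_score_scan(model, rc)
    expect_equal(a$max_score, b$max_score)
    expect_equal(a$hit_count, b$hit_count)
  }
})

test_that("flanking ratio PFMs follow the stated pseudocount arithmetic", {
  # identical flank sets -> all-ones ratio
  fl <- c("ACGT", "TTAA", "GGCC")
  r <- build_flanking_pfm(fl, fl, flank_bp = 2L)
  expect_equal(unname(r$mat), matrix(1, 4, 4))
  expect_equal(r$type, "ratio")

  # methylated all-A vs unmethylated all-C, 4 sequences each, eps 0.01
  rm_ <- build_flanking_pfm(rep("AAAA", 4), rep("CCCC", 4), flank_bp = 2L,
                            pseudocount = 0.01)
  expect_equal(unname(rm_$mat["A", ]), rep(401, 4))

  # a single sequence per set stays finite thanks to the pseudocount
  one <- build_flanking_pfm("AC", "GT", flank_bp = 1L)
  expect_true(all(is.finite(one$mat)) && all(one$mat > 0))

  expect_error(build_flanking_pfm("AAAA", "CC", flank_bp = 2L), "length")
})

test_that("ratio entries approach 1 when both flank sets share a distribution", {
  set.seed(41)
  draw <- function(n) vapply(seq_len(n), function(i)
    random_seq(8, probs = c(0.4, 0.1, 0.2, 0.3)), character(1))
  small <- build_flanking_pfm(draw(20), draw(20), flank_bp = 4L)
  big <- build_flanking_pfm(draw(5000), draw(5000), flank_bp = 4L)
  err_small <- mean(abs(log2(small$mat)))
  err_big <- mean(abs(log2(big$mat)))
  expect_lt(err_big, err_small)
  expect_lt(err_big, 0.1)
})

test_that("flanking features take the max CpG-window score per model", {
  labeled <- small_labeled()
  models <- build_flanking_models(labeled)
  expect_named(models, c("cell4", "cell20", "generic4", "generic20"))
  rec <- labeled[[1]]
  v <- flanking_features(rec, models)
  expect_length(v, 4L)
  expect_true(all(is.finite(v)))

  # no CpGs -> zeros
  none <- record_from_seq(strrep("AT", 50))
  expect_equal(unname(flanking_features(none, models)), rep(0, 4))

  # single-CpG island: feature equals that CpG's own window score
  one <- record_from_seq(paste0(strrep("A", 30), "CG", strrep("T", 30)))
  v1 <- flanking_features(one, models)
  m <- models$cell4
  fb <- ncol(m$w) / 2
  off <- 30L
  flank <- paste0(substr(one$seq, off - fb + 1, off),
                  substr(one$seq, off + 3, off + 2 + fb))
  codes <- match(strsplit(flank, "")[[1]], c("A", "C", "G", "T"))
  expect_equal(v1[["cell4"]],
               sum(m$w[cbind(codes, seq_len(ncol(m$w)))]))
})

test_that("splice-site features report 4 max scores plus a hit total", {
  fx <- small_fixture()
  rec <- small_labeled()[[2]]
  v <- splice_site_features(rec, fx$splice_models)
  expect_length(v, 5L)
  expect_equal(v[["total_hits"]], sum(vapply(
    fx$splice_models, function(m) weight_score_scan(m, rec$seq)$hit_count,
    numeric(1))))
  expect_error(splice_site_features(rec, list()), "no splice")
})

test_that("a planted donor consensus registers at least one hit", {
  fx <- small_fixture()
  donor <- fx$splice_models[[1]]
  consensus <- paste(c("A", "C", "G", "T")[apply(donor$w, 2, which.max)],
                     collapse = "")
  rec <- record_from_seq(paste0(random_seq(60), consensus, random_seq(60)))
  v <- splice_site_features(rec, fx$splice_models)
  expect_gte(v[["total_hits"]], 1)
})

test_that("tfbs features are one max score per PFM plus a log hit total", {
  fx <- small_fixture()
  rec <- small_labeled()[[3]]
  v <- tfbs_features(rec, fx$tfbs_models)
  expect_length(v, length(fx$tfbs_models) + 1L)
  hits <- sum(vapply(fx$tfbs_models, function(m)
    weight_score_scan(m, rec$seq)$hit_count, numeric(1)))
  expect_equal(v[["log_total_hits"]], log10(1 + hits))
  expect_equal(unname(tfbs_features(rec, list())), 0)
})

test_that("the significance filter removes weak PFMs, keeps planted ones", {
  seqs <- vapply(1:5, function(i) random_seq(400), character(1))
  weak <- weight_score_model(uniform_pfm(6), epsilon = 0)
  planted <- weight_score_model(consensus_pfm(substr(seqs[1], 50, 57)))
  kept <- filter_pfm_library(list(weak = weak, planted = planted), seqs)
  expect_named(kept, "planted")
  expect_length(filter_pfm_library(list(), seqs), 0L)
})
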