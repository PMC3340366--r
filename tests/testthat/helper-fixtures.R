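# shared fixtures and brute-force oracles for the test suite

.cache <- new.env(parent = emptyenv())

# small fixture with a reduced PFM library; built once per test run
small_fixture_dir <- function() {
  if (is.null(.cache$small_dir)) {
    d <- file.path(tempdir(), "cgimeth_small_fixture")
    unlink(d, recursive = TRUE)
    generate_fixture(
      fixture_spec(seed = 42L, n_islands = 12L,
                   chroms = c("chr1", "chr21"),
                   pfm_library_size = 15L, n_octamers = 256L),
      d)
    .cache$small_dir <- d
  }
  .cache$small_dir
}

small_fixture <- function() {
  if (is.null(.cache$small_fx))
    .cache$small_fx <- read_fixture(small_fixture_dir())
  .cache$small_fx
}

# labeled records + full feature resources for the small fixture
small_labeled <- function() {
  if (is.null(.cache$small_labeled)) {
    fx <- small_fixture()
    recs <- make_islands(fx$genome, fx$islands)
    .cache$small_labeled <- suppressWarnings(
      label_islands(recs, fx$methylation))
  }
  .cache$small_labeled
}

small_resources <- function() {
  if (is.null(.cache$small_res)) {
    fx <- small_fixture()
    fm <- build_flanking_models(small_labeled())
    .cache$small_res <- feature_resources(
      fx$genome, fx$bundle, fx$histone_tracks, fx$conservation,
      fx$tfbs_models, fx$splice_models, fx$octamer_table, fm)
  }
  .cache$small_res
}

# fixture under the reference configuration (456 TFBS PFMs, 23 tracks,
# 43 structure parameters), few islands
reference_fixture <- function() {
  if (is.null(.cache$ref_fx)) {
    d <- file.path(tempdir(), "cgimeth_reference_fixture")
    unlink(d, recursive = TRUE)
    generate_fixture(fixture_spec(seed = 7L, n_islands = 6L,
                                  chroms = c("chr1", "chr21")), d)
    .cache$ref_fx <- read_fixture(d)
  }
  .cache$ref_fx
}

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# make a minimal island record directly from a window sequence
record_from_seq <- function(seq, island_start = 0L, island_end = nchar(seq),
                            win_start = 0L, chrom = "chrT",
                            id = "test") {
  rec <- list(id = id, chrom = chrom,
              start = win_start + island_start,
              end = win_start + island_end,
              win_start = win_start, win_end = win_start + nchar(seq),
              seq = seq,
              cpg = {
                m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
                if (m[1] == -1L) integer(0) else as.integer(m) - 1L
              },
              meth_fraction = NA_real_, label = NA_character_)
  class(rec) <- "CpGIslandRecord"
  rec
}

ctx_from_seq <- function(seq, ...) sequence_context(record_from_seq(seq, ...))

# --- brute-force oracles -----------------------------------------------

# O(n * 4^k) k-mer counter via substring comparison
oracle_kmer_counts <- function(seq, k) {
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[
    , k:1, drop = FALSE], 1, paste, collapse = ""))
  wins <- substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq))
  vapply(kmers, function(m) sum(wins == m), numeric(1))
}

# O(n * m) interval intersection with clipped overlap widths
oracle_overlaps <- function(df, chrom, start, end) {
  hit <- df$chrom == chrom & df$start < end & df$end > start
  out <- df[hit, , drop = FALSE]
  out$overlap_bp <- pmin(out$end, end) - pmax(out$start, start)
  out
}

# per-position PFM rescoring over both strands, N windows NA
oracle_scan <- function(w, seq) {
  L <- ncol(w)
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score1 <- function(window, mat) {
    b <- strsplit(window, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(L), function(j)
      mat[b[j], j], numeric(1)))
  }
  vapply(1:(n - L + 1), function(i) {
    win <- substr(seq, i, i + L - 1)
    f <- score1(win, w)
    rc <- paste(rev(unname(comp[strsplit(win, "")[[1]]])), collapse = "")
    r <- score1(rc, w)
    if (is.na(f)) NA_real_ else max(f, r)
  }, numeric(1))
}
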