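#' Sequence-derived feature classes
#'
#' Feature classes computable from the island sequence alone. k-mer and
#' attribute features use the un-extended island sequence; periodic and
#' closest-CpG features use the CpGs inside the island. "N" bases are
#' excluded from nucleotide counts and break k-mer windows.
#'
#' @name features_sequence
NULL

#' Build a sequence context for an island record
#'
#' @param rec A `CpGIslandRecord`.
#' @return List with the island sequence (`seq`), window sequence
#'   (`window_seq`), island length (`n`), window length (`win_len`),
#'   island-relative CpG offsets (`cpg`), and per-base counts
#'   (`base_counts`, named A/C/G/T/N).
#' @export
sequence_context <- function(rec) {
  seq <- island_seq(rec)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bc <- vapply(c("A", "C", "G", "T", "N"),
               function(b) sum(chars == b), integer(1))
  list(seq = seq, window_seq = rec$seq, n = nchar(seq),
       win_len = nchar(rec$seq),
       cpg = island_cpg_offsets(rec), base_counts = bc)
}

# count occurrences of a fixed dinucleotide (overlapping) in a string
count_2mer <- function(seq, mer) {
  m <- gregexpr(mer, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' CpG-island attribute features (7)
#'
#' Computed on the un-extended island sequence of length N:
#' CG content `(#C+#G)/N`; CG ratio `#CpG/(N/2)`; CG observed/expected
#' ratio `(#CpG * N)/(#C * #G)` (0 when `#C * #G == 0`); CG/TG ratio on the
#' forward strand `#CG/(#TG + 1)`; CG/TG ratio on both strands
#' `2 * #CG/(#TG + #CA + 1)` (CA is the reverse complement of TG, CG is
#' self-complementary); AT/CG ratio `(#A+#T)/(#C+#G+1)`; and a 0/1 flag
#' for overlap with a coding region. The `+1` pseudocounts keep ratios
#' finite on degenerate sequences.
#'
#' @param ctx A [sequence_context()].
#' @param coding_overlap Logical flag: does the island overlap a coding
#'   region?
#' @return Named numeric vector of 7 features.
#' @export
cgi_attributes <- function(ctx, coding_overlap = FALSE) {
  n <- ctx$n
  if (n == 0) stop("empty island sequence")
  bc <- ctx$base_counts
  ncg <- length(ctx$cpg)
  ntg <- count_2mer(ctx$seq, "TG")
  nca <- count_2mer(ctx$seq, "CA")
  obs_exp <- if (bc[["C"]] * bc[["G"]] == 0) 0
             else ncg * n / (bc[["C"]] * bc[["G"]])
  c(cg_content = (bc[["C"]] + bc[["G"]]) / n,
    cg_ratio = ncg / (n / 2),
    obs_exp = obs_exp,
    cg_tg_fwd = ncg / (ntg + 1),
    cg_tg_both = 2 * ncg / (ntg + nca + 1),
    at_cg = (bc[["A"]] + bc[["T"]]) / (bc[["C"]] + bc[["G"]] + 1),
    coding = as.numeric(isTRUE(coding_overlap)))
}

# overlapping k-mer counts over ACGT (windows containing N are dropped),
# in lexicographic order
kmer_counts <- function(seq, k) {
  x <- Biostrings::DNAString(seq)
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k)
  cnt[order(names(cnt))]
}

#' Dinucleotide frequency features (16)
#'
#' Overlapping dinucleotide counts over the island sequence, each divided
#' by the island length N (so the 16 features sum to `(N-1)/N` on an
#' N-free sequence), in lexicographic order AA..TT.
#'
#' @param ctx A [sequence_context()].
#' @return Named numeric vector of 16 features.
#' @export
dinucleotide_features <- function(ctx) {
  if (ctx$n < 2) stop("island shorter than 2 bp")
  kmer_counts(ctx$seq, 2) / ctx$n
}

#' Tetranucleotide features (257)
#'
#' 256 length-normalized tetranucleotide frequencies (lexicographic) plus
#' one raw (not length-normalized) count of `AGCT` occurrences, the core
#' motif of the Alu repeat.
#'
#' @param ctx A [sequence_context()].
#' @return Named numeric vector of 257 features (last one `AGCT_count`).
#' @export
tetranucleotide_features <- function(ctx) {
  if (ctx$n < 4) stop("island shorter than 4 bp")
  cnt <- kmer_counts(ctx$seq, 4)
  c(cnt / ctx$n, AGCT_count = unname(cnt[["AGCT"]]))
}

#' Periodic CpG distance features (15)
#'
#' For each distance d in 9, 18, 27, 36, 45 (multiples of nine) the
#' downstream score is the fraction of island CpGs that have another CpG
#' starting exactly d bp downstream; upstream analogously (10 features).
#' The same pair of scores is computed for d = 48 (2 features). Three sums
#' complete the class: the sum of the ten multiple-of-nine scores, the sum
#' of the two 48-bp scores, and the grand sum of those two sums.
#'
#' @param ctx A [sequence_context()].
#' @return Named numeric vector of 15 features (all zero, with a warning,
#'   when the island has no CpG).
#' @export
periodic_cpg_features <- function(ctx) {
  dists <- c(9L, 18L, 27L, 36L, 45L)
  nms <- c(paste0("d", dists, "_down"), paste0("d", dists, "_up"),
           "d48_down", "d48_up", "sum_nine", "sum_48", "sum_all")
  cpg <- ctx$cpg
  if (!length(cpg)) {
    warning("island has no CpG; periodic features set to 0")
    return(stats::setNames(numeric(15), nms))
  }
  score <- function(d, dir) mean((cpg + dir * d) %in% cpg)
  down <- vapply(dists, score, numeric(1), dir = 1)
  up <- vapply(dists, score, numeric(1), dir = -1)
  d48 <- c(score(48L, 1), score(48L, -1))
  sums <- c(sum(down) + sum(up), sum(d48))
  stats::setNames(c(down, up, d48, sums, sum(sums)), nms)
}

#' Closest-CpG distance features (6)
#'
#' For every CpG in the island, the distances to its three nearest other
#' CpGs are collected (fewer when the island has fewer than 4 CpGs). The
#' features are the three smallest values of the pooled collection and the
#' means of the pooled rank-1, rank-2 and rank-3 distances. With fewer
#' CpGs than needed, the pooled minima are padded with the largest pooled
#' value and an empty rank falls back to the mean of the highest available
#' rank; with fewer than 2 CpGs all six features take the window length as
#' a finite sentinel.
#'
#' @param ctx A [sequence_context()].
#' @return Named numeric vector of 6 features.
#' @export
closest_cpg_features <- function(ctx) {
  nms <- c("min1", "min2", "min3", "mean_rank1", "mean_rank2", "mean_rank3")
  cpg <- ctx$cpg
  if (length(cpg) < 2)
    return(stats::setNames(rep(ctx$win_len, 6), nms))
  ranked <- lapply(seq_along(cpg), function(i) {
    d <- sort(abs(cpg[-i] - cpg[i]))
    d[seq_len(min(3L, length(d)))]
  })
  pooled <- sort(unlist(ranked))
  mins <- pooled[pmin(1:3, length(pooled))]   # pad with the largest value
  rank_mean <- numeric(3)
  for (r in 1:3) {
    vals <- unlist(lapply(ranked, function(d) if (length(d) >= r) d[r]))
    rank_mean[r] <- if (length(vals)) mean(vals) else rank_mean[r - 1]
  }
  stats::setNames(c(mins, rank_mean), nms)
}
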