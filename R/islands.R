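#' CpG island records
#'
#' A `CpGIslandRecord` bundles an island's coordinates, its extended
#' analysis window (island plus primer length plus a fixed pad up- and
#' downstream, clipped to chromosome bounds), the window sequence, the
#' 0-based offsets of all CpG dinucleotides within the window, and an
#' optional methylation fraction / binary label.
#'
#' @name CpGIslandRecord
NULL

#' Extend an island interval to its analysis window
#'
#' The window is `[start - primer_len - pad, end + primer_len + pad)`,
#' clipped to `[0, chrom_len)`.
#'
#' @param start,end 0-based half-open island interval.
#' @param chrom_len Chromosome length (bp).
#' @param primer_len Primer sequence length (bp) to add on each side.
#' @param pad Fixed extension (bp) on each side; default 500.
#' @return Integer vector `c(start, end)` of the clipped window.
#' @export
extend_window <- function(start, end, chrom_len, primer_len = 0L, pad = 500L) {
  stopifnot(start < end, chrom_len >= end)
  w <- c(start - primer_len - pad, end + primer_len + pad)
  pmin(pmax(w, 0L), chrom_len)
}

#' Build CpG island records from island coordinates and a genome
#'
#' @param genome A `GenomeSequence`.
#' @param islands An `IntervalTrack` of island coordinates (the `name`
#'   column, if present, supplies ids).
#' @param primer_len Primer length used for window extension.
#' @param pad Window pad (bp) on each side.
#' @return List of `CpGIslandRecord` objects with fields `id`, `chrom`,
#'   `start`, `end`, `win_start`, `win_end`, `seq` (window sequence),
#'   `cpg` (0-based CpG offsets within the window), `meth_fraction`
#'   (`NA` until labeled) and `label` (`NA`).
#' @export
make_islands <- function(genome, islands, primer_len = 0L, pad = 500L) {
  df <- islands$df
  ids <- if ("name" %in% names(df) && !anyNA(df$name)) df$name
         else sprintf("CGI_%04d", seq_len(nrow(df)))
  lapply(seq_len(nrow(df)), function(i) {
    chrom <- df$chrom[i]
    if (!chrom %in% names(genome$seqs))
      stop("island on unknown chromosome: ", chrom)
    win <- extend_window(df$start[i], df$end[i], genome$lengths[[chrom]],
                         primer_len = primer_len, pad = pad)
    seq <- subsequence(genome, chrom, win[1], win[2])
    rec <- list(id = ids[i], chrom = chrom,
                start = df$start[i], end = df$end[i],
                win_start = win[1], win_end = win[2],
                seq = seq, cpg = cpg_offsets(seq),
                meth_fraction = NA_real_, label = NA_character_)
    class(rec) <- "CpGIslandRecord"
    rec
  })
}

#' @export
print.CpGIslandRecord <- function(x, ...) {
  cat(sprintf("CpGIslandRecord %s %s:%d-%d (window %d-%d), %d CpGs in window",
              x$id, x$chrom, x$start, x$end, x$win_start, x$win_end,
              length(x$cpg)))
  if (!is.na(x$label)) cat(sprintf(", label=%s", x$label))
  cat("\n")
  invisible(x)
}

# island sequence (un-extended) of a record
island_seq <- function(rec) {
  substr(rec$seq, rec$start - rec$win_start + 1L, rec$end - rec$win_start)
}

# 0-based offsets, within the *island* sequence, of CpGs fully inside the
# island interval
island_cpg_offsets <- function(rec) {
  rel <- rec$cpg + rec$win_start          # genome coordinates
  keep <- rel >= rec$start & rel <= rec$end - 2L
  rec$cpg[keep] - (rec$start - rec$win_start)
}

# genome-coordinate CpG starts inside the island interval
island_cpg_positions <- function(rec) {
  pos <- rec$cpg + rec$win_start
  pos[pos >= rec$start & pos <= rec$end - 2L]
}
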