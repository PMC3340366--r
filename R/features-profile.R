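#' Table- and track-driven feature classes
#'
#' DNA-structure energies from an octamer parameter table, evolutionary
#' conservation from a scored element track, and histone-modification
#' features from signal tracks. Structure and conservation are computed on
#' the island interval; histone signal on the extended analysis window.
#'
#' @name features_profile
NULL

#' Read an octamer DNA-structure energy table
#'
#' Tab-separated: a header line `octamer<TAB>param1..paramK`, then one row
#' per octamer with K numeric structural energy values. Either all 4^8
#' octamers are present or a default row keyed `*` supplies values for
#' octamers missing from the table.
#'
#' @param path File path.
#' @return An `OctamerEnergyTable`: list with `values` (numeric matrix,
#'   octamers as rownames), `default` (numeric vector or `NULL`),
#'   `params` (parameter names) and `k` (parameter count).
#' @export
read_octamer_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  octs <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric energy values in ", path)
  rownames(mat) <- octs
  dflt <- if ("*" %in% octs) mat["*", ] else NULL
  values <- mat[octs != "*", , drop = FALSE]
  if (is.null(dflt) && nrow(values) < 4^8)
    stop("octamer table must list all 4^8 octamers or provide a '*' default row")
  structure(list(values = values, default = dflt,
                 params = colnames(mat), k = ncol(mat)),
            class = "OctamerEnergyTable")
}

#' DNA-structure energy features (K, 43 in the reference configuration)
#'
#' Feature k is the mean of the k-th octamer energy value over all
#' overlapping 8-mer windows of the island sequence; windows containing N
#' are skipped. When every window is skipped the features fall back to a
#' zero sentinel with a warning.
#'
#' @param island_seq Island sequence (length >= 8).
#' @param table An `OctamerEnergyTable`.
#' @return Named numeric vector of `table$k` features.
#' @export
dna_structure_features <- function(island_seq, table) {
  n <- nchar(island_seq)
  if (n < 8) stop("island shorter than 8 bp")
  wins <- substring(island_seq, 1:(n - 7L), 8:n)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  nm <- table$params
  if (!length(wins)) {
    warning("all 8-mer windows contain N; structure features set to 0")
    return(stats::setNames(numeric(table$k), nm))
  }
  idx <- match(wins, rownames(table$values))
  known <- !is.na(idx)
  if (!all(known) && is.null(table$default))
    stop("octamer missing from table and no default row: ", wins[!known][1])
  total <- colSums(table$values[idx[known], , drop = FALSE])
  if (any(!known)) total <- total + table$default * sum(!known)
  stats::setNames(total / length(wins), nm)
}

#' Evolutionary conservation features (4)
#'
#' From a scored conserved-element track: mean and maximum score of the
#' elements overlapping the island (0 when none), the fraction of island
#' base pairs covered by elements (clipped, overlaps merged), and the
#' element count.
#'
#' @param rec A `CpGIslandRecord`.
#' @param element_track Scored `IntervalTrack`.
#' @return Named numeric vector of 4 features.
#' @export
conservation_features <- function(rec, element_track) {
  hits <- track_overlaps(element_track, rec$chrom, rec$start, rec$end)
  len <- rec$end - rec$start
  if (!nrow(hits))
    return(c(mean_score = 0, max_score = 0, covered_frac = 0, n_elements = 0))
  cov <- IRanges::reduce(IRanges::IRanges(pmax(hits$start, rec$start) + 1L,
                                          pmin(hits$end, rec$end)))
  c(mean_score = mean(hits$score), max_score = max(hits$score),
    covered_frac = sum(IRanges::width(cov)) / len,
    n_elements = nrow(hits))
}

#' Histone-modification features (4 per track)
#'
#' Per signal track, over the island's extended analysis window: interval
#' count, overlap density (total clipped overlap bp divided by window
#' length), mean score of overlapping intervals (0 when none) and maximum
#' score. Tracks are processed in the supplied order; 23 tracks give the
#' reference configuration's 92 features.
#'
#' @param rec A `CpGIslandRecord`.
#' @param tracks Named list of scored `IntervalTrack`s.
#' @return Named numeric vector of `4 * length(tracks)` features.
#' @export
histone_features <- function(rec, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("histone tracks must be named")
  wl <- rec$win_end - rec$win_start
  out <- numeric(0)
  for (nm in names(tracks)) {
    hits <- track_overlaps(tracks[[nm]], rec$chrom, rec$win_start,
                           rec$win_end)
    v <- c(count = nrow(hits),
           density = sum(hits$overlap_bp) / wl,
           mean_score = if (nrow(hits)) mean(hits$score) else 0,
           max_score = if (nrow(hits)) max(hits$score) else 0)
    names(v) <- paste(nm, names(v), sep = "_")
    out <- c(out, v)
  }
  out
}
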