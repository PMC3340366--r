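#' Binary labeling of CpG islands from methylation measurements
#'
#' Functions converting per-CpG (bisulfite amplicon) or per-probe
#' measurements into binary island labels, plus the training/validation
#' split protocols.
#'
#' @name labeling
NULL

#' Read a tab-separated methylation table
#'
#' Columns: chrom, start, end, value (no header). Values may be fractions
#' in \[0,1\] or scores on a 0--1000 scale; see [detect_scale()].
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_methylation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("methylation table needs 4 columns: ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  df[, 1:4]
}

#' Detect the scale of methylation values
#'
#' Auto-detection recognizes only the \[0,1\] fraction scale and the
#' 0--1000 score scale; anything else must be declared explicitly.
#'
#' @param values Numeric vector.
#' @return Scale factor to divide by (1 or 1000).
#' @export
detect_scale <- function(values) {
  mx <- max(values, na.rm = TRUE)
  mn <- min(values, na.rm = TRUE)
  if (mn < 0) stop("negative methylation values; declare the scale explicitly")
  if (mx <= 1) return(1)
  if (mx <= 1000) return(1000)
  stop("cannot auto-detect methylation scale (max = ", mx,
       "); declare it explicitly")
}

#' Average overlapping observations per CpG
#'
#' Each CpG dinucleotide occupies positions `[p, p + 2)`. Its value is the
#' arithmetic mean of all observations whose interval overlaps those two
#' base pairs; CpGs covered by no observation are `NA` (missing is a state,
#' not an error).
#'
#' @param observations Data frame (`chrom`, `start`, `end`, `value`),
#'   values already on the \[0,1\] scale.
#' @param cpg_positions 0-based genome start positions of CpGs.
#' @param chrom Chromosome of the CpGs.
#' @return Numeric vector of per-CpG fractions (NA where uncovered).
#' @export
average_observations_per_cpg <- function(observations, cpg_positions, chrom) {
  obs <- observations[observations$chrom == chrom, , drop = FALSE]
  vapply(cpg_positions, function(p) {
    hit <- obs$start < p + 2L & obs$end > p
    if (!any(hit)) NA_real_ else mean(obs$value[hit])
  }, numeric(1))
}

#' Label one island from its per-CpG fractions
#'
#' The island methylation fraction is the unweighted mean of all
#' non-missing per-CpG fractions; the island is called methylated iff the
#' fraction is strictly greater than `threshold`.
#'
#' @param per_cpg_fractions Numeric vector (NAs allowed).
#' @param threshold Methylation call threshold; default 0.60.
#' @return List with `fraction` and `label` (`"methylated"` /
#'   `"unmethylated"`).
#' @export
label_island <- function(per_cpg_fractions, threshold = 0.60) {
  vals <- per_cpg_fractions[!is.na(per_cpg_fractions)]
  if (!length(vals)) stop("island has no covered CpGs; cannot label")
  fr <- mean(vals)
  list(fraction = fr,
       label = if (fr > threshold) "methylated" else "unmethylated")
}

#' Label a set of island records from a methylation table
#'
#' Applies [average_observations_per_cpg()] and [label_island()] to every
#' record. Islands whose CpGs are all uncovered are excluded (with a
#' message naming them).
#'
#' @param records List of `CpGIslandRecord`.
#' @param observations Methylation table data frame; `scale` divides the
#'   values (`"auto"` uses [detect_scale()]).
#' @param threshold Call threshold.
#' @param scale `"auto"`, or a numeric divisor.
#' @param min_minority Warn if the minority class ends up below this size
#'   (severely imbalanced sets make k-fold SVM training unreliable).
#' @return List of labeled records (subset of input); attribute
#'   `excluded` holds ids of islands without covered CpGs.
#' @export
label_islands <- function(records, observations, threshold = 0.60,
                          scale = "auto", min_minority = 35L) {
  s <- if (identical(scale, "auto")) detect_scale(observations$value)
       else as.numeric(scale)
  observations$value <- observations$value / s
  if (any(observations$value < 0 | observations$value > 1))
    stop("methylation values outside [0,1] after rescaling")
  excluded <- character(0)
  out <- list()
  for (rec in records) {
    fr <- average_observations_per_cpg(observations,
                                       island_cpg_positions(rec), rec$chrom)
    if (all(is.na(fr))) {
      excluded <- c(excluded, rec$id)
      next
    }
    lab <- label_island(fr, threshold)
    rec$meth_fraction <- lab$fraction
    rec$label <- lab$label
    out <- c(out, list(rec))
  }
  if (length(excluded))
    message(length(excluded), " island(s) without covered CpGs excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  counts <- table(factor(vapply(out, `[[`, character(1), "label"),
                         levels = c("unmethylated", "methylated")))
  if (length(out) && min(counts) < min_minority)
    warning(sprintf(
      "severely imbalanced dataset: minority class has %d instance(s)",
      min(counts)))
  attr(out, "excluded") <- excluded
  attr(out, "class_counts") <- counts
  out
}

#' Map probe-level scores to per-island methylation fractions
#'
#' Each island's value is the mean of the (rescaled) scores of all probes
#' overlapping it; a probe spanning several islands contributes to each of
#' their means. Probes overlapping no island are discarded and counted;
#' islands with zero overlapping probes are excluded and counted.
#'
#' @param probe_track `IntervalTrack` with a `score` column.
#' @param islands `IntervalTrack` of island intervals (ids in `name`).
#' @param scale `"auto"` or numeric divisor for the probe scores.
#' @return Data frame (`id`, `chrom`, `start`, `end`, `fraction`,
#'   `n_probes`), with attributes `discarded_probes` and
#'   `excluded_islands`.
#' @export
map_probes_to_islands <- function(probe_track, islands, scale = "auto") {
  s <- if (identical(scale, "auto")) detect_scale(probe_track$df$score)
       else as.numeric(scale)
  pdf <- probe_track$df
  pdf$value <- pdf$score / s
  idf <- islands$df
  ids <- if ("name" %in% names(idf)) idf$name else sprintf("CGI_%04d",
                                                           seq_len(nrow(idf)))
  hits <- GenomicRanges::findOverlaps(islands$gr, probe_track$gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  fraction <- tapply(pdf$value[si], factor(qi, levels = seq_len(nrow(idf))),
                     mean)
  n_probes <- tabulate(qi, nbins = nrow(idf))
  out <- data.frame(id = ids, chrom = idf$chrom, start = idf$start,
                    end = idf$end, fraction = as.numeric(fraction),
                    n_probes = n_probes, stringsAsFactors = FALSE)
  excluded <- out$id[out$n_probes == 0]
  out <- out[out$n_probes > 0, , drop = FALSE]
  attr(out, "discarded_probes") <- nrow(pdf) - length(unique(si))
  attr(out, "excluded_islands") <- excluded
  out
}

#' Remove ambiguously methylated islands
#'
#' Islands whose methylation fraction lies inside the closed interval
#' `[low, high]` cannot be assigned a confident binary state (for example
#' when half of the overlapping probes are methylated) and are removed.
#'
#' @param island_fractions Data frame with a `fraction` column (as from
#'   [map_probes_to_islands()]), or a list of labeled records.
#' @param low,high Inclusive ambiguity bounds; defaults 0.40 and 0.60.
#' @return Filtered object of the same type; attribute `removed` gives the
#'   removal count.
#' @export
remove_ambiguous <- function(island_fractions, low = 0.40, high = 0.60) {
  if (is.data.frame(island_fractions)) {
    keep <- island_fractions$fraction < low | island_fractions$fraction > high
    out <- island_fractions[keep, , drop = FALSE]
    attr(out, "removed") <- sum(!keep)
  } else {
    fr <- vapply(island_fractions, `[[`, numeric(1), "meth_fraction")
    keep <- fr < low | fr > high
    out <- island_fractions[keep]
    attr(out, "removed") <- sum(!keep)
  }
  out
}

#' Split a labeled dataset for training and validation
#'
#' Two recipes: `stratified_fraction` draws a training set of the given
#' fraction preserving the methylated proportion (per-class rounded
#' counts, seeded); `chromosome_holdout` puts every island of the named
#' chromosome in the training set and all others in the test set.
#'
#' @param records List of labeled `CpGIslandRecord`s.
#' @param recipe A list from [split_stratified()] or [split_chrom_holdout()].
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all records) and the `recipe`.
#' @export
make_split <- function(records, recipe) {
  labels <- vapply(records, `[[`, character(1), "label")
  n <- length(records)
  if (recipe$kind == "stratified_fraction") {
    f <- recipe$fraction
    if (!is.numeric(f) || f <= 0 || f >= 1)
      stop("fraction must lie strictly between 0 and 1")
    set.seed(recipe$seed)
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- round(f * length(idx))
      train <- c(train, sort(sample(idx, k)))
    }
    train <- sort(train)
  } else if (recipe$kind == "chromosome_holdout") {
    chroms <- vapply(records, `[[`, character(1), "chrom")
    train <- which(chroms == recipe$chrom)
    if (!length(train))
      stop("no islands on holdout chromosome ", recipe$chrom)
  } else stop("unknown split recipe: ", recipe$kind)
  list(train = train, test = setdiff(seq_len(n), train), recipe = recipe)
}

#' @rdname make_split
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer RNG seed.
#' @export
split_stratified <- function(fraction, seed) {
  list(kind = "stratified_fraction", fraction = fraction, seed = seed)
}

#' @rdname make_split
#' @param chrom Chromosome whose islands form the training set.
#' @export
split_chrom_holdout <- function(chrom) {
  list(kind = "chromosome_holdout", chrom = chrom)
}
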