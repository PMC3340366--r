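#' PFM weight-score models and scanning
#'
#' One shared scanner serves all motif feature classes. A
#' `WeightScoreModel` wraps a `PFM` as a 4 x L additive weight matrix:
#' `log2((f + eps) / bg)` for frequency PFMs, `log2(R)` for ratio PFMs.
#' The score of a sequence window is the sum of the weights of its bases;
#' on this log2-odds scale a score of about 5 marks a good match and
#' scores below 1 are insignificant. Both strands are scanned and the
#' per-position maximum of the two orientations is used; windows
#' containing N are skipped.
#'
#' @name weight_score
NULL

#' Build a weight-score model from a PFM
#'
#' @param pfm A `PFM` (frequency or ratio type).
#' @param epsilon Pseudo-frequency added inside the log for frequency
#'   PFMs; default 0.01.
#' @param theta Hit threshold; positions scoring at least `theta` count as
#'   hits. Default 5.
#' @return A `WeightScoreModel`.
#' @export
weight_score_model <- function(pfm, epsilon = 0.01, theta = 5) {
  stopifnot(inherits(pfm, "PFM"))
  w <- if (pfm$type == "frequency") {
    log2(sweep(pfm$mat + epsilon, 1, pfm$background, "/"))
  } else {
    log2(pfm$mat)
  }
  structure(list(name = pfm$name, w = w, type = pfm$type,
                 epsilon = epsilon, theta = theta),
            class = "WeightScoreModel")
}

# A/C/G/T -> 1..4, anything else NA
base_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# additive per-position scores of weight matrix w over integer codes;
# positions whose window touches an NA code come out NA
score_positions <- function(w, codes) {
  L <- ncol(w)
  npos <- length(codes) - L + 1L
  if (npos < 1) return(numeric(0))
  s <- numeric(npos)
  for (j in seq_len(L)) {
    s <- s + w[, j][codes[j:(j + npos - 1L)]]
  }
  unname(s)
}

#' Scan a sequence with a weight-score model
#'
#' Scores every window position on both strands (the reverse-strand score
#' at a position is the score of the reverse complement of that window)
#' and combines them with a per-position maximum.
#'
#' @param model A `WeightScoreModel`.
#' @param sequence Character string (ACGTN) at least as long as the PFM.
#' @return List with `max_score` (maximum positional score; 0 when no
#'   position is scoreable), `hit_count` (positions scoring >= `theta`)
#'   and `scores` (per-position combined scores, NA where skipped).
#' @export
weight_score_scan <- function(model, sequence) {
  L <- ncol(model$w)
  if (nchar(sequence) < L)
    stop("sequence shorter than PFM length ", L)
  codes <- base_codes(sequence)
  fwd <- score_positions(model$w, codes)
  w_rc <- model$w[4:1, L:1, drop = FALSE]
  rev <- score_positions(w_rc, codes)
  s <- pmax(fwd, rev)
  ok <- !is.na(s)
  list(max_score = if (any(ok)) max(s[ok]) else 0,
       hit_count = sum(s[ok] >= model$theta),
       scores = s)
}

#' Build a ratio PFM from methylated and unmethylated CpG flanks
#'
#' Computes column-stochastic frequency PFMs (with pseudocount) from the
#' two flank sets and divides the methylated by the unmethylated matrix
#' element-wise. Flank strings are the concatenated upstream and
#' downstream flanks of a CpG, excluding the CpG itself, hence of length
#' `2 * flank_bp`.
#'
#' @param methylated_flanks,unmethylated_flanks Character vectors of flank
#'   strings (all of length `2 * flank_bp`).
#' @param flank_bp Flank size in bp (4 or 20 in the reference
#'   configuration).
#' @param pseudocount Pseudocount added to each base count; default 0.01.
#' @return A ratio-type `PFM`.
#' @export
build_flanking_pfm <- function(methylated_flanks, unmethylated_flanks,
                               flank_bp, pseudocount = 0.01) {
  stopifnot(length(methylated_flanks) > 0, length(unmethylated_flanks) > 0)
  L <- 2L * flank_bp
  if (any(nchar(c(methylated_flanks, unmethylated_flanks)) != L))
    stop("all flanks must have length ", L)
  count_mat <- function(flanks) {
    m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- do.call(rbind, strsplit(flanks, "", fixed = TRUE))
    for (j in seq_len(L)) {
      tb <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
      m[, j] <- as.numeric(tb)
    }
    m
  }
  fm <- normalize_counts(count_mat(methylated_flanks), pseudocount)
  fu <- normalize_counts(count_mat(unmethylated_flanks), pseudocount)
  pfm(fm / fu, name = sprintf("flank_ratio_%dbp", flank_bp), type = "ratio",
      pseudocount = pseudocount)
}

# flank string (2*flank_bp, CpG excluded) around a window-relative CpG
# offset; NULL when it would run off the window or contains N
cpg_flank_string <- function(win_seq, off, flank_bp) {
  lo <- off - flank_bp
  hi <- off + 2L + flank_bp
  if (lo < 0 || hi > nchar(win_seq)) return(NULL)
  s <- paste0(substr(win_seq, lo + 1L, off),
              substr(win_seq, off + 3L, hi))
  if (grepl("N", s, fixed = TRUE)) NULL else s
}

#' Collect CpG flank strings from labeled island records
#'
#' @param records Labeled `CpGIslandRecord`s.
#' @param flank_bp Flank size.
#' @return List with character vectors `methylated` and `unmethylated`
#'   (flanks of island CpGs, grouped by the island label).
#' @export
collect_cpg_flanks <- function(records, flank_bp) {
  out <- list(methylated = character(0), unmethylated = character(0))
  for (rec in records) {
    if (is.na(rec$label)) next
    offs <- island_cpg_offsets(rec) + (rec$start - rec$win_start)
    fl <- unlist(lapply(offs, function(o)
      cpg_flank_string(rec$seq, o, flank_bp)))
    out[[rec$label]] <- c(out[[rec$label]], fl)
  }
  out
}

#' Build the four flanking-sequence models from training data
#'
#' Four ratio-PFM models separate methylated from unmethylated CpG
#' contexts: a cell-type-specific and a generic (reference) model for each
#' flank size (4 and 20 bp). When no separate reference set is supplied
#' the generic models are built from the same records (documented
#' fallback).
#'
#' @param records Labeled training records (cell-type specific).
#' @param reference_records Optional labeled records pooled across cell
#'   types for the generic models.
#' @param flank_bps Flank sizes; default `c(4, 20)`.
#' @param pseudocount Pseudocount for PFM construction.
#' @return Named list of 4 `WeightScoreModel`s: `cell4`, `cell20`,
#'   `generic4`, `generic20`.
#' @export
build_flanking_models <- function(records, reference_records = NULL,
                                  flank_bps = c(4L, 20L),
                                  pseudocount = 0.01) {
  if (is.null(reference_records)) reference_records <- records
  build1 <- function(recs, fb) {
    fl <- collect_cpg_flanks(recs, fb)
    weight_score_model(build_flanking_pfm(fl$methylated, fl$unmethylated,
                                          fb, pseudocount))
  }
  models <- list(cell4 = build1(records, flank_bps[1]),
                 cell20 = build1(records, flank_bps[2]),
                 generic4 = build1(reference_records, flank_bps[1]),
                 generic20 = build1(reference_records, flank_bps[2]))
  models
}

#' CpG flanking-sequence features (4)
#'
#' One feature per flanking model: the maximum weight score over all
#' CpG-centered flank windows of the island (forward orientation; flank
#' models are built from forward-strand contexts). Islands without a CpG
#' (or whose flank windows all leave the analysis window) score 0.
#'
#' @param rec A `CpGIslandRecord`.
#' @param models List of 4 `WeightScoreModel`s from
#'   [build_flanking_models()].
#' @return Named numeric vector of 4 features.
#' @export
flanking_features <- function(rec, models) {
  offs <- island_cpg_offsets(rec) + (rec$start - rec$win_start)
  vapply(models, function(m) {
    fb <- ncol(m$w) %/% 2L
    if (!length(offs)) return(0)
    scores <- vapply(offs, function(o) {
      s <- cpg_flank_string(rec$seq, o, fb)
      if (is.null(s)) return(NA_real_)
      sum(m$w[cbind(base_codes(s), seq_len(ncol(m$w)))])
    }, numeric(1))
    if (all(is.na(scores))) 0 else max(scores, na.rm = TRUE)
  }, numeric(1))
}

#' Splice-site features (5)
#'
#' Maximum weight scores of the four splice-site PFMs (GT-AG and GC-AG
#' donor/acceptor) over the island analysis window, plus the total hit
#' count across all four models at their hit threshold.
#'
#' @param rec A `CpGIslandRecord`.
#' @param splice_models List of 4 `WeightScoreModel`s.
#' @return Named numeric vector of 5 features.
#' @export
splice_site_features <- function(rec, splice_models) {
  if (!length(splice_models)) stop("no splice-site PFMs supplied")
  scans <- lapply(splice_models, weight_score_scan, sequence = rec$seq)
  v <- vapply(scans, `[[`, numeric(1), "max_score")
  names(v) <- names(splice_models)
  c(v, total_hits = sum(vapply(scans, `[[`, numeric(1), "hit_count")))
}

#' Transcription-factor binding-site features (library size + 1)
#'
#' One maximum-weight-score feature per PFM in the library, scanned over
#' the island analysis window, plus `log10(1 + total hit count)` across
#' the whole library.
#'
#' @param rec A `CpGIslandRecord`.
#' @param models List of `WeightScoreModel`s (the significance-filtered
#'   TFBS library).
#' @return Named numeric vector of `length(models) + 1` features (last one
#'   `log_total_hits`).
#' @export
tfbs_features <- function(rec, models) {
  if (!length(models))
    return(c(log_total_hits = 0))
  scans <- lapply(models, weight_score_scan, sequence = rec$seq)
  v <- vapply(scans, `[[`, numeric(1), "max_score")
  names(v) <- vapply(models, `[[`, character(1), "name")
  hits <- sum(vapply(scans, `[[`, numeric(1), "hit_count"))
  c(v, log_total_hits = log10(1 + hits))
}

#' Filter a PFM library by significance on training sequences
#'
#' Keeps PFMs whose maximum weight score over all supplied training
#' sequences reaches `min_max_score`; matrices that never score at least 1
#' lack significance and are removed.
#'
#' @param models List of `WeightScoreModel`s.
#' @param sequences Character vector of training island sequences.
#' @param min_max_score Retention threshold; default 1.
#' @return Filtered list of models.
#' @export
filter_pfm_library <- function(models, sequences, min_max_score = 1.0) {
  keep <- vapply(models, function(m) {
    best <- max(vapply(sequences, function(s) {
      if (nchar(s) < ncol(m$w)) return(-Inf)
      weight_score_scan(m, s)$max_score
    }, numeric(1)))
    best >= min_max_score
  }, logical(1))
  models[keep]
}
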