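#' Scored genomic interval tracks
#'
#' An `IntervalTrack` stores 0-based half-open genomic intervals with an
#' optional score and arbitrary attribute columns (repeat family, SNP
#' alleles, feature type, ...). Overlap queries are served by
#' [GenomicRanges::findOverlaps()] on an index built at construction time.
#'
#' @param df Data frame with at least `chrom`, `start`, `end`; optionally
#'   `score`, `name` and further attribute columns.
#' @param name Track name.
#' @return An `IntervalTrack`.
#' @export
interval_track <- function(df, name = "track") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("interval with start >= end at record %d (%s:%d-%d)",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  # per-chromosome NCList index for fast single-region queries
  idx <- split(seq_len(nrow(df)), df$chrom)
  nclists <- lapply(idx, function(i)
    IRanges::NCList(IRanges::IRanges(df$start[i] + 1L, df$end[i])))
  structure(list(name = name, df = df, gr = gr, row_idx = idx,
                 nclists = nclists),
            class = "IntervalTrack")
}

#' @export
print.IntervalTrack <- function(x, ...) {
  cat(sprintf("IntervalTrack '%s': %d record(s) on %d chromosome(s)\n",
              x$name, nrow(x$df),
              length(unique(x$df$chrom))))
  invisible(x)
}

#' Number of records in a track
#' @param x An `IntervalTrack`.
#' @param ... Unused.
#' @export
length.IntervalTrack <- function(x) nrow(x$df)

#' Query a track for intervals overlapping a region
#'
#' @param track An `IntervalTrack`.
#' @param chrom Chromosome.
#' @param start,end 0-based half-open query interval.
#' @return The subset of the track's data frame that intersects the query
#'   (any overlap of at least 1 bp), in input order, with an extra column
#'   `overlap_bp` giving the clipped overlap width.
#' @export
track_overlaps <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "IntervalTrack"), start < end)
  nc <- track$nclists[[chrom]]
  if (is.null(nc)) {
    idx <- integer(0)
  } else {
    hits <- IRanges::findOverlaps(IRanges::IRanges(start + 1L, end), nc)
    idx <- sort(track$row_idx[[chrom]][S4Vectors::subjectHits(hits)])
  }
  out <- track$df[idx, , drop = FALSE]
  if (nrow(out)) {
    out$overlap_bp <- pmin(out$end, end) - pmax(out$start, start)
  } else {
    out$overlap_bp <- integer(0)
  }
  out
}

#' Read a BED or bedGraph file into an IntervalTrack
#'
#' BED columns: chrom, start, end, \[name, score, strand, ...\]. bedGraph
#' columns: chrom, start, end, score. Coordinates are 0-based half-open and
#' read verbatim.
#'
#' @param path File path.
#' @param dialect `"bed"` (score in column 5) or `"bedgraph"` (score in
#'   column 4).
#' @param name Track name (defaults to the file base name).
#' @return An `IntervalTrack`.
#' @export
read_bed <- function(path, dialect = c("bed", "bedgraph"), name = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = paste0("V", 1:12), fill = TRUE)
  if (ncol(raw) < 3 || nrow(raw) == 0) stop("BED file needs >= 3 columns: ", path)
  df <- data.frame(chrom = as.character(raw$V1),
                   start = as.integer(raw$V2),
                   end = as.integer(raw$V3),
                   stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s line %d: start >= end", path, bad[1]))
  if (dialect == "bedgraph") {
    df$score <- as.numeric(raw$V4)
  } else {
    if (!all(is.na(raw$V4))) df$name <- as.character(raw$V4)
    if (!all(is.na(raw$V5))) df$score <- suppressWarnings(as.numeric(raw$V5))
    if (!all(is.na(raw$V6))) df$strand <- as.character(raw$V6)
  }
  interval_track(df, name = name)
}

#' Read a GTF-like annotation file into gene/transcript/exon tracks
#'
#' Expects a tab-separated file with columns chrom, source, feature, start,
#' end, score, strand, frame, attributes; `feature` is one of `gene`,
#' `transcript` or `exon` and the attribute column holds
#' `key "value";` pairs (`gene_id`, `transcript_id`, `gene_biotype`).
#' Coordinates in the file are 1-based inclusive (GTF convention) and are
#' converted to the package-internal 0-based half-open convention.
#'
#' @param path File path.
#' @return List of `IntervalTrack`s: `genes`, `transcripts`, `exons`. Gene
#'   records carry `gene_id`, `biotype`, `strand` and a derived `tss`
#'   column (0-based position: `start` for `+`, `end - 1` for `-`).
#' @export
read_gtf <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 9) stop("GTF-like file needs 9 columns: ", path)
  names(raw) <- c("chrom", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attributes")
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, ' "[^"]*"'), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0(key, ' "'), a))) > 0,
           sub('"$', "", sub(paste0(key, ' "'), "", m)), NA_character_)
  }
  base <- data.frame(chrom = raw$chrom,
                     start = raw$start - 1L,  # to 0-based half-open
                     end = raw$end,
                     strand = raw$strand,
                     gene_id = attr_get(raw$attributes, "gene_id"),
                     stringsAsFactors = FALSE)
  base$transcript_id <- attr_get(raw$attributes, "transcript_id")
  base$biotype <- attr_get(raw$attributes, "gene_biotype")
  pick <- function(feat) base[raw$feature == feat, , drop = FALSE]
  genes <- pick("gene")
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  list(genes = interval_track(genes, "genes"),
       transcripts = interval_track(pick("transcript"), "transcripts"),
       exons = interval_track(pick("exon"), "exons"))
}
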