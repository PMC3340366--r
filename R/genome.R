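#' Read a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a `GenomeSequence` object:
#' uppercase-normalized per-chromosome nucleotide strings restricted to the
#' A/C/G/T/N alphabet. Record ids are taken as the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A `GenomeSequence` object (list with `seqs`, a named character
#'   vector, and `lengths`, a named integer vector of chromosome lengths).
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    offender <- ids[bad][1L]
    ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
    stop(sprintf("FASTA record '%s' contains non-ACGTN character '%s'",
                 offender, ch))
  }
  if (anyDuplicated(ids)) stop("duplicated FASTA record ids")
  structure(
    list(seqs = seqs, lengths = vapply(seqs, nchar, integer(1))),
    class = "GenomeSequence"
  )
}

#' Construct a GenomeSequence from named character strings
#'
#' @param seqs Named character vector of chromosome sequences (ACGTN).
#' @return A `GenomeSequence`.
#' @export
genome_from_strings <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) stop("sequences must be over ACGTN")
  structure(
    list(seqs = seqs, lengths = vapply(seqs, nchar, integer(1))),
    class = "GenomeSequence"
  )
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence with", length(x$seqs), "chromosome(s):\n")
  print(x$lengths)
  invisible(x)
}

#' Extract a subsequence (0-based half-open coordinates)
#'
#' @param genome A `GenomeSequence`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Character string of length `end - start`.
#' @export
subsequence <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "GenomeSequence"))
  if (!chrom %in% names(genome$seqs)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 0 || end > len || start > end)
    stop(sprintf("interval [%d,%d) outside chromosome %s (length %d)",
                 start, end, chrom, len))
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' Chromosome lengths of a genome
#' @param genome A `GenomeSequence`.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) genome$lengths

# reverse complement of an ACGTN string
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# 0-based start offsets of all "CG" dinucleotides in a sequence string
cpg_offsets <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Write a GenomeSequence to FASTA
#' @param genome A `GenomeSequence`.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seqs)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seqs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
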