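#' Position frequency matrices
#'
#' A `PFM` holds a 4 x L matrix (rows A, C, G, T) of per-position nucleotide
#' frequencies together with a background model. Two types exist:
#' `"frequency"` PFMs whose columns sum to 1, and `"ratio"` PFMs (built by
#' [build_flanking_pfm()]) whose entries are element-wise quotients of two
#' frequency PFMs and carry no column-sum constraint.
#'
#' @param mat 4 x L nonnegative numeric matrix, rownames A/C/G/T.
#' @param name PFM name.
#' @param type `"frequency"` or `"ratio"`.
#' @param pseudocount Pseudocount used at construction.
#' @param background Named background nucleotide frequencies (sum 1).
#' @return A `PFM` object.
#' @export
pfm <- function(mat, name = "pfm", type = c("frequency", "ratio"),
                pseudocount = 0.01,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  type <- match.arg(type)
  stopifnot(is.matrix(mat), nrow(mat) == 4, ncol(mat) >= 1, all(mat >= 0))
  rownames(mat) <- c("A", "C", "G", "T")
  background <- background[c("A", "C", "G", "T")]
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (type == "frequency") {
    cs <- colSums(mat)
    if (any(abs(cs - 1) > 1e-6))
      stop("frequency PFM columns must sum to 1")
  }
  structure(list(name = name, mat = mat, type = type,
                 pseudocount = pseudocount, background = background),
            class = "PFM")
}

#' @export
print.PFM <- function(x, ...) {
  cat(sprintf("PFM '%s' (%s), length %d\n", x$name, x$type, ncol(x$mat)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Length (number of positions) of a PFM
#' @param pfm A `PFM`.
#' @return Integer motif length.
#' @export
pfm_length <- function(pfm) ncol(pfm$mat)

# counts (4 x L) -> column-stochastic frequency matrix with pseudocount
normalize_counts <- function(counts, pseudocount) {
  cs <- colSums(counts)
  if (any(cs == 0) && pseudocount <= 0)
    stop("PFM column of all zeros and no pseudocount")
  sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
}

#' Read a JASPAR-style PFM library
#'
#' Parses text of the form
#' \preformatted{>MA0001 name
#' A [ 10  2  0 ]
#' C [  0  8  1 ]
#' G [  1  0 12 ]
#' T [  2  3  0 ]}
#' (brackets optional). Counts are normalized to column-stochastic
#' frequencies after adding `pseudocount` to every cell.
#'
#' @param path File path.
#' @param pseudocount Pseudocount added to each count before normalization.
#' @param background Background nucleotide frequencies.
#' @return List of `PFM` objects (empty list, with a warning, for an empty
#'   file).
#' @export
read_pfm_library <- function(path, pseudocount = 0.01,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty PFM library: ", path)
    return(list())
  }
  heads <- grep("^>", lines)
  if (!length(heads) || heads[1] != 1)
    stop("malformed PFM library (expected '>' header first): ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4)
      stop(sprintf("PFM '%s': expected 4 nucleotide rows, got %d",
                   name, length(block)))
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = parts[1], counts = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop(sprintf("PFM '%s': rows must be labelled A/C/G/T", name))
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(is.na(counts))) stop(sprintf("PFM '%s': non-numeric count", name))
    out[[i]] <- pfm(normalize_counts(counts, pseudocount), name = name,
                    type = "frequency", pseudocount = pseudocount,
                    background = background)
  }
  out
}

#' Write PFMs (as counts) in JASPAR-style text
#'
#' @param counts_list Named list of 4 x L count matrices (rows A/C/G/T).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pfm_library <- function(counts_list, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(counts_list)) {
    m <- counts_list[[nm]]
    writeLines(paste0(">", nm), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
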