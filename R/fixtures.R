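#' Synthetic fixture generation
#'
#' Generates a self-contained directory of genome, islands, annotations,
#' signal tracks, PFM libraries, octamer table and per-CpG methylation
#' table with controllable class signal, so that every pipeline stage is
#' testable without external downloads. Islands are planted as
#' CpG-enriched, GC-rich segments on a CpG-depleted background;
#' methylated islands carry a configurable mean shift (in sd units) in
#' every histone track and a small base-composition delta. One RNG stream
#' per file type is derived from the master seed, so adding a track type
#' does not perturb the others. Output is byte-identical for a fixed spec.
#'
#' @param seed Master seed (integer).
#' @param n_islands Total number of islands, split evenly over `chroms`.
#' @param chroms Chromosome names.
#' @param island_len_range Island length range (bp).
#' @param methylated_fraction Fraction of islands labeled methylated; the
#'   emitted truth table contains exactly `round(fraction * n_islands)`
#'   methylated islands.
#' @param histone_shift Mean shift (in sd units, sd = 1) added to every
#'   histone track score over methylated islands.
#' @param composition_delta Base-composition delta: methylated island
#'   sequences shift this much probability mass from C/G to A/T.
#' @param periodic_enrichment Probability that a planted CpG in a
#'   methylated island is placed 9 bp downstream of the previous one.
#' @param n_histone_tracks Number of histone signal tracks (23 in the
#'   reference configuration).
#' @param pfm_library_size TFBS PFM library size (456 reference).
#' @param octamer_params Number of DNA-structure parameters (43 reference).
#' @param n_octamers Octamer rows written to the energy table (a `*`
#'   default row covers the rest).
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_islands = 30L,
                         chroms = c("chr1", "chr2", "chr21"),
                         island_len_range = c(600L, 1200L),
                         methylated_fraction = 0.3,
                         histone_shift = 2,
                         composition_delta = 0.05,
                         periodic_enrichment = 0,
                         n_histone_tracks = 23L,
                         pfm_library_size = 456L,
                         octamer_params = 43L,
                         n_octamers = 2048L) {
  stopifnot(methylated_fraction >= 0, methylated_fraction <= 1,
            periodic_enrichment >= 0, periodic_enrichment <= 1,
            n_islands >= length(chroms))
  structure(list(seed = as.integer(seed), n_islands = as.integer(n_islands),
                 chroms = chroms,
                 island_len_range = as.integer(island_len_range),
                 methylated_fraction = methylated_fraction,
                 histone_shift = histone_shift,
                 composition_delta = composition_delta,
                 periodic_enrichment = periodic_enrichment,
                 n_histone_tracks = as.integer(n_histone_tracks),
                 pfm_library_size = as.integer(pfm_library_size),
                 octamer_params = as.integer(octamer_params),
                 n_octamers = as.integer(n_octamers)),
            class = "FixtureSpec")
}

.histone_track_names <- function(n) {
  base <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K9me1", "H3K9me2",
            "H3K9me3", "H3K27me1", "H3K27me2", "H3K27me3", "H3K36me1",
            "H3K36me3", "H3K79me1", "H3K79me2", "H3K79me3", "H3R2me1",
            "H3R2me2", "H4K20me1", "H4K20me3", "H4R3me2", "H2BK5me1",
            "H2AZ", "PolII", "CTCF")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("track%02d", seq_len(n - length(base))))
}

# derived per-stream seed, kept below 2^31
.stream_seed <- function(seed, k) (seed * 1009L + k * 9973L) %% 2147483647L

.rand_seq <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a fixture directory
#'
#' Writes genome FASTA, island BED, GTF-like gene annotation, SNP, repeat,
#' self-alignment and conservation BEDs, one bedGraph per histone track,
#' JASPAR-style TFBS and splice-site PFM libraries, an octamer energy
#' table, a per-CpG methylation table consistent with the island truth
#' labels, plus `truth.json` and `spec.json`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created; must not contain a prior fixture).
#' @return Invisibly, `dir`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "histone"), showWarnings = FALSE)

  n_chrom <- length(spec$chroms)
  per_chrom <- rep(spec$n_islands %/% n_chrom, n_chrom)
  rem <- spec$n_islands %% n_chrom
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
  margin <- 1500L
  slot <- max(spec$island_len_range) + 2800L
  chrom_len <- stats::setNames(per_chrom * slot + 2L * margin, spec$chroms)

  # --- island placement and labels -------------------------------------
  set.seed(.stream_seed(spec$seed, 1L))
  islands <- list()
  idx <- 0L
  for (ci in seq_len(n_chrom)) {
    for (j in seq_len(per_chrom[ci])) {
      idx <- idx + 1L
      len <- sample(seq(spec$island_len_range[1], spec$island_len_range[2]),
                    1L)
      start <- margin + (j - 1L) * slot + sample(0:800, 1L)
      islands[[idx]] <- data.frame(
        id = sprintf("CGI_%04d", idx), chrom = spec$chroms[ci],
        start = start, end = start + len, stringsAsFactors = FALSE)
    }
  }
  isl <- do.call(rbind, islands)
  n_meth <- round(spec$methylated_fraction * nrow(isl))
  meth_idx <- sort(sample(nrow(isl), n_meth))
  isl$label <- "unmethylated"
  isl$label[meth_idx] <- "methylated"

  # --- genome sequence --------------------------------------------------
  set.seed(.stream_seed(spec$seed, 2L))
  bg_probs <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  seqs <- character(n_chrom)
  names(seqs) <- spec$chroms
  for (ci in seq_len(n_chrom)) {
    s <- strsplit(.rand_seq(chrom_len[ci], bg_probs), "")[[1]]
    # deplete background CpGs: most CG dinucleotides lose their G
    cg <- which(s[-length(s)] == "C" & s[-1] == "G")
    kill <- cg[stats::runif(length(cg)) < 0.8]
    s[kill + 1L] <- "A"
    seqs[ci] <- paste(s, collapse = "")
  }
  # plant islands: GC-rich segment with inserted CpGs
  for (i in seq_len(nrow(isl))) {
    len <- isl$end[i] - isl$start[i]
    delta <- if (isl$label[i] == "methylated") spec$composition_delta else 0
    probs <- c(A = 0.175 + delta / 2, C = 0.325 - delta / 2,
               G = 0.325 - delta / 2, T = 0.175 + delta / 2)
    s <- strsplit(.rand_seq(len, probs), "")[[1]]
    n_cg <- max(2L, len %/% 12L)
    pos <- integer(0)
    p <- sample(3:12, 1L)
    while (p < len - 2L && length(pos) < n_cg) {
      pos <- c(pos, p)
      step <- if (isl$label[i] == "methylated" &&
                  stats::runif(1) < spec$periodic_enrichment) 9L
              else sample(6:18, 1L)
      p <- p + step
    }
    s[pos] <- "C"; s[pos + 1L] <- "G"
    chrom <- isl$chrom[i]
    substr(seqs[chrom], isl$start[i] + 1L, isl$end[i]) <-
      paste(s, collapse = "")
  }
  genome <- genome_from_strings(seqs)
  write_genome_fasta(genome, file.path(dir, "genome.fa"))
  utils::write.table(isl[, c("chrom", "start", "end", "id")],
                     file.path(dir, "islands.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # --- methylation table (consistent with labels) ----------------------
  set.seed(.stream_seed(spec$seed, 3L))
  obs <- list()
  fractions <- numeric(nrow(isl))
  for (i in seq_len(nrow(isl))) {
    seq_i <- subsequence(genome, isl$chrom[i], isl$start[i], isl$end[i])
    cpg <- cpg_offsets(seq_i) + isl$start[i]
    methylated <- isl$label[i] == "methylated"
    v <- NULL
    for (try in 1:100) {
      cand <- if (methylated) stats::rbeta(length(cpg), 8, 2)
              else stats::rbeta(length(cpg), 2, 8)
      if ((methylated && mean(cand) > 0.65) ||
          (!methylated && mean(cand) < 0.35)) { v <- cand; break }
    }
    if (is.null(v)) {  # adjust toward a safe mean; practically unreachable
      target <- if (methylated) 0.75 else 0.25
      v <- pmin(pmax(cand + (target - mean(cand)), 0.01), 0.99)
    }
    fractions[i] <- mean(v)
    dup <- stats::runif(length(cpg)) < 0.3
    d <- pmin(0.05, v, 1 - v)
    for (j in seq_along(cpg)) {
      if (dup[j]) {
        obs[[length(obs) + 1L]] <- data.frame(
          chrom = isl$chrom[i], start = cpg[j], end = cpg[j] + 2L,
          value = c(v[j] + d[j], v[j] - d[j]))
      } else {
        obs[[length(obs) + 1L]] <- data.frame(
          chrom = isl$chrom[i], start = cpg[j], end = cpg[j] + 2L,
          value = v[j])
      }
    }
  }
  obs <- do.call(rbind, obs)
  obs$value <- round(obs$value, 6)
  utils::write.table(obs, file.path(dir, "methylation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  isl$fraction <- round(fractions, 6)

  # --- gene annotation --------------------------------------------------
  set.seed(.stream_seed(spec$seed, 4L))
  gtf <- character(0)
  gi <- 0L
  for (i in seq_len(nrow(isl))) {
    if (stats::runif(1) > 0.9) next
    gi <- gi + 1L
    methylated <- isl$label[i] == "methylated"
    off <- if (methylated) sample(2000:6000, 1L) else sample(0:400, 1L)
    tss <- min(isl$start[i] + off, chrom_len[isl$chrom[i]] - 2500L)
    glen <- sample(2000:5000, 1L)
    gend <- min(tss + glen, chrom_len[isl$chrom[i]])
    biotype <- if (stats::runif(1) < 0.8) "protein_coding" else "lincRNA"
    gid <- sprintf("GENE%04d", gi)
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', gid, biotype)
    gtf <- c(gtf, sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\t%s",
                          isl$chrom[i], tss + 1L, gend, attr_g))
    for (t in seq_len(sample(1:3, 1L))) {
      tid <- sprintf("%s.T%d", gid, t)
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                        gid, tid, biotype)
      gtf <- c(gtf, sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s",
                            isl$chrom[i], tss + 1L, gend, attr_t))
    }
    cand <- seq(tss, gend - 350L, by = 50L)
    n_ex <- min(sample(1:4, 1L), length(cand))
    bounds <- sort(sample(cand, n_ex))
    for (e in seq_len(n_ex)) {
      es <- bounds[e]
      ee <- min(es + sample(80:300, 1L), gend)
      attr_e <- sprintf('gene_id "%s"; transcript_id "%s.T1"; gene_biotype "%s";',
                        gid, gid, biotype)
      gtf <- c(gtf, sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\t%s",
                            isl$chrom[i], es + 1L, ee, attr_e))
    }
  }
  writeLines(gtf, file.path(dir, "genes.gtf"))

  # --- SNPs, repeats, self-alignments, conservation --------------------
  set.seed(.stream_seed(spec$seed, 5L))
  bed_df <- function(n, chrom, len_range, chrlen, name_pool = NULL,
                     scores = NULL) {
    starts <- sort(sample(seq_len(chrlen - max(len_range) - 1L), n))
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    df <- data.frame(chrom = chrom, start = starts,
                     end = pmin(starts + lens, chrlen))
    if (!is.null(name_pool))
      df$name <- sample(name_pool, n, replace = TRUE)
    if (!is.null(scores)) df$score <- scores
    df
  }
  snps <- list(); reps <- list(); sas <- list(); cons <- list()
  for (ci in seq_len(n_chrom)) {
    cl <- chrom_len[ci]
    snps[[ci]] <- bed_df(max(5L, cl %/% 1500L), spec$chroms[ci], c(1L, 1L),
                         cl, name_pool = c("A/G", "T/C", "C/T", "G/A",
                                           "A/C", "G/T"))
    reps[[ci]] <- bed_df(max(4L, cl %/% 2500L), spec$chroms[ci],
                         c(150L, 400L), cl,
                         name_pool = c("AluY", "AluSx", "L1", "MIR", "L2"))
    sas[[ci]] <- bed_df(max(3L, cl %/% 4000L), spec$chroms[ci],
                        c(200L, 900L), cl, name_pool = "self")
    nc <- max(3L, cl %/% 3000L)
    cons[[ci]] <- bed_df(nc, spec$chroms[ci], c(100L, 300L), cl,
                         name_pool = "elem",
                         scores = round(stats::runif(nc, 0.1, 1), 3))
  }
  wr_bed <- function(lst, path, with_score = FALSE) {
    df <- do.call(rbind, lst)
    cols <- c("chrom", "start", "end", "name",
              if (with_score) "score")
    utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  wr_bed(snps, file.path(dir, "snps.bed"))
  wr_bed(reps, file.path(dir, "repeats.bed"))
  wr_bed(sas, file.path(dir, "selfalign.bed"))
  wr_bed(cons, file.path(dir, "conservation.bed"), with_score = TRUE)

  # --- histone tracks ---------------------------------------------------
  set.seed(.stream_seed(spec$seed, 6L))
  track_names <- .histone_track_names(spec$n_histone_tracks)
  for (tn in track_names) {
    base <- stats::runif(1, 2, 6)
    rows <- list()
    for (i in seq_len(nrow(isl))) {
      mu <- base + if (isl$label[i] == "methylated") spec$histone_shift else 0
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = isl$chrom[i], start = max(0L, isl$start[i] - 200L),
        end = isl$end[i] + 200L,
        score = round(stats::rnorm(1, mu, 1), 4))
    }
    # background intervals away from islands
    for (ci in seq_len(n_chrom)) {
      nb <- 5L
      st <- sample(seq(0L, chrom_len[ci] - 600L, by = 200L), nb)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = spec$chroms[ci], start = st, end = st + 500L,
        score = round(stats::rnorm(nb, base, 1), 4))
    }
    df <- do.call(rbind, rows)
    utils::write.table(df, file.path(dir, "histone",
                                     paste0(tn, ".bedGraph")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  # --- PFM libraries ----------------------------------------------------
  set.seed(.stream_seed(spec$seed, 7L))
  n_planted <- min(6L, spec$pfm_library_size)
  pfms <- list()
  for (k in seq_len(spec$pfm_library_size - n_planted)) {
    L <- sample(6:12, 1L)
    m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(L)) {
      p <- stats::rgamma(4, 1); p <- p / sum(p)
      m[, j] <- as.numeric(stats::rmultinom(1, 20, p))
    }
    pfms[[sprintf("RAND%03d", k)]] <- m
  }
  # planted-consensus PFMs taken from island 8-mers so the significance
  # filter has something to keep
  src <- sample(nrow(isl), n_planted)
  for (k in seq_len(n_planted)) {
    s <- subsequence(genome, isl$chrom[src[k]], isl$start[src[k]],
                     isl$end[src[k]])
    at <- sample(nchar(s) - 8L, 1L)
    mer <- substr(s, at, at + 7L)
    m <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    cols <- match(strsplit(mer, "")[[1]], c("A", "C", "G", "T"))
    for (j in 1:8) if (!is.na(cols[j])) m[cols[j], j] <- 50
    pfms[[sprintf("PLANT%02d", k)]] <- m
  }
  write_pfm_library(pfms, file.path(dir, "pfms_tfbs.txt"))

  splice <- list(
    donor_GT = cbind(c(5, 5, 5, 5), c(5, 5, 5, 5), c(1, 1, 58, 1),
                     c(1, 1, 1, 58), c(40, 5, 10, 5), c(50, 3, 4, 3),
                     c(5, 5, 45, 5)),
    donor_GC = cbind(c(5, 5, 5, 5), c(5, 5, 5, 5), c(1, 1, 58, 1),
                     c(1, 58, 1, 1), c(40, 5, 10, 5), c(50, 3, 4, 3),
                     c(5, 5, 45, 5)),
    acceptor_AG = cbind(c(5, 20, 5, 30), c(5, 25, 5, 25), c(58, 1, 1, 1),
                        c(1, 1, 58, 1), c(15, 15, 15, 15)),
    acceptor_AG2 = cbind(c(5, 30, 5, 20), c(5, 20, 5, 30), c(58, 1, 1, 1),
                         c(1, 1, 58, 1), c(15, 15, 15, 15)))
  splice <- lapply(splice, function(m) {
    rownames(m) <- c("A", "C", "G", "T"); m
  })
  write_pfm_library(splice, file.path(dir, "pfms_splice.txt"))

  # --- octamer table ----------------------------------------------------
  set.seed(.stream_seed(spec$seed, 8L))
  octs <- unique(vapply(seq_len(spec$n_octamers), function(i)
    .rand_seq(8L, rep(0.25, 4)), character(1)))
  vals <- matrix(round(stats::rnorm(length(octs) * spec$octamer_params), 4),
                 nrow = length(octs))
  tab <- data.frame(octamer = c(octs, "*"),
                    rbind(vals, round(stats::rnorm(spec$octamer_params), 4)))
  names(tab)[-1] <- sprintf("param%02d", seq_len(spec$octamer_params))
  utils::write.table(tab, file.path(dir, "octamer_energies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- truth and provenance --------------------------------------------
  truth <- list(
    islands = isl[, c("id", "chrom", "start", "end", "label", "fraction")],
    params = list(seed = spec$seed, histone_shift = spec$histone_shift,
                  methylated_fraction = spec$methylated_fraction,
                  composition_delta = spec$composition_delta,
                  periodic_enrichment = spec$periodic_enrichment),
    class_counts = as.list(table(isl$label)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back the ground truth of a generated fixture
#'
#' @param dir Fixture directory.
#' @return List with `islands` (data frame incl. `label`), `params`
#'   (generative parameters) and `class_counts`.
#' @export
truth_table <- function(dir) {
  path <- file.path(dir, "truth.json")
  if (!file.exists(path))
    stop("not a fixture directory (no truth.json): ", dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load a fixture directory into pipeline resources
#'
#' @param dir Fixture directory written by [generate_fixture()].
#' @param theta Hit threshold passed to the weight-score models.
#' @return List with `genome`, `islands` (`IntervalTrack`), `bundle`,
#'   `histone_tracks`, `conservation`, `tfbs_models`, `splice_models`,
#'   `octamer_table`, `methylation` (data frame) and `truth`.
#' @export
read_fixture <- function(dir, theta = 5) {
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  islands <- read_bed(file.path(dir, "islands.bed"), name = "islands")
  ann <- read_gtf(file.path(dir, "genes.gtf"))
  bundle <- annotation_bundle(
    genes = ann$genes, transcripts = ann$transcripts, exons = ann$exons,
    snps = read_bed(file.path(dir, "snps.bed"), name = "snps"),
    repeats = read_bed(file.path(dir, "repeats.bed"), name = "repeats"),
    selfalign = read_bed(file.path(dir, "selfalign.bed"),
                         name = "selfalign"))
  hist_files <- sort(list.files(file.path(dir, "histone"),
                                pattern = "\\.bedGraph$",
                                full.names = TRUE))
  histone_tracks <- lapply(hist_files, read_bed, dialect = "bedgraph")
  names(histone_tracks) <- sub("\\.bedGraph$", "", basename(hist_files))
  tfbs <- read_pfm_library(file.path(dir, "pfms_tfbs.txt"))
  splice <- read_pfm_library(file.path(dir, "pfms_splice.txt"))
  splice_models <- lapply(splice, weight_score_model, theta = theta)
  names(splice_models) <- vapply(splice, `[[`, character(1), "name")
  list(genome = genome, islands = islands, bundle = bundle,
       histone_tracks = histone_tracks,
       conservation = read_bed(file.path(dir, "conservation.bed"),
                               name = "conservation"),
       tfbs_models = lapply(tfbs, weight_score_model, theta = theta),
       splice_models = splice_models,
       octamer_table = read_octamer_table(
         file.path(dir, "octamer_energies.tsv")),
       methylation = read_methylation_table(file.path(dir,
                                                      "methylation.tsv")),
       truth = truth_table(dir))
}
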