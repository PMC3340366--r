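#' Annotation-driven feature classes
#'
#' Feature classes requiring annotation tracks: distances to transcription
#' start sites, genomic attributes, repeat/Alu-Y/self-alignment features
#' and SNP features. All distances are measured from the island midpoint;
#' "no neighbor found" cases use a finite sentinel (the search radius for
#' windowed searches, the chromosome length for global ones) so that
#' feature vectors stay SVM-friendly.
#'
#' @name features_annotation
NULL

#' Bundle annotation tracks for feature generation
#'
#' @param genes,transcripts,exons `IntervalTrack`s as from [read_gtf()].
#' @param snps `IntervalTrack`; SNP alleles expected in the `name` column
#'   as `"X/Y"`.
#' @param repeats `IntervalTrack`; repeat family in the `name` column
#'   (`AluY` recognized case-insensitively).
#' @param selfalign `IntervalTrack` of DNA/DNA self-alignments.
#' @return An `AnnotationBundle` (plain list, classed).
#' @export
annotation_bundle <- function(genes, transcripts, exons, snps, repeats,
                              selfalign) {
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 snps = snps, repeats = repeats, selfalign = selfalign),
            class = "AnnotationBundle")
}

island_midpoint <- function(rec) (rec$start + rec$end) %/% 2L

#' Distance-to-TSS features (4)
#'
#' d1 = distance (bp) from the island midpoint to the nearest transcription
#' start site of any gene; d2 = the same restricted to protein-coding
#' genes. Emitted as `log10(1 + d1)`, `log10(1 + d2)`, `d1 / L` and
#' `d2 / L` with L the chromosome length. A distance of 0 is reported when
#' the island overlaps a TSS. With no (protein-coding) gene on the
#' chromosome, the chromosome length serves as sentinel distance.
#'
#' @param rec A `CpGIslandRecord`.
#' @param genes Gene `IntervalTrack` with `tss` and `biotype` columns.
#' @param chrom_len Chromosome length (bp).
#' @return Named numeric vector of 4 features.
#' @export
tss_distance_features <- function(rec, genes, chrom_len) {
  mid <- island_midpoint(rec)
  g <- genes$df[genes$df$chrom == rec$chrom, , drop = FALSE]
  dist_to <- function(tss) {
    if (!length(tss)) return(chrom_len)
    # zero if the island body overlaps a TSS, else midpoint distance
    inside <- any(tss >= rec$start & tss < rec$end)
    if (inside) 0 else min(abs(tss - mid))
  }
  d1 <- dist_to(g$tss)
  d2 <- dist_to(g$tss[!is.na(g$biotype) & g$biotype == "protein_coding"])
  c(log_any = log10(1 + d1), log_coding = log10(1 + d2),
    norm_any = d1 / chrom_len, norm_coding = d2 / chrom_len)
}

#' Genomic attribute features (11)
#'
#' Repetitive fraction (self-alignment bp overlapping the island divided
#' by island length), number and total length of overlapping genes, number,
#' total and mean length of overlapping exons, transcript count of the
#' overlapping genes and transcripts per gene, island length, CpG base
#' fraction (`2 * #CpG / length`) and the mean distance between
#' consecutive island CpGs (island length as sentinel with fewer than two
#' CpGs). Gene/exon lengths are full feature lengths; overlap fractions
#' use clipped base pairs.
#'
#' @param rec A `CpGIslandRecord`.
#' @param bundle An `AnnotationBundle`.
#' @return Named numeric vector of 11 features.
#' @export
genomic_attribute_features <- function(rec, bundle) {
  len <- rec$end - rec$start
  sa <- track_overlaps(bundle$selfalign, rec$chrom, rec$start, rec$end)
  genes <- track_overlaps(bundle$genes, rec$chrom, rec$start, rec$end)
  exons <- track_overlaps(bundle$exons, rec$chrom, rec$start, rec$end)
  tx <- bundle$transcripts$df
  ntx <- if (nrow(genes)) sum(tx$gene_id %in% genes$gene_id) else 0L
  cpg <- island_cpg_offsets(rec)
  cpg_gap <- if (length(cpg) >= 2) mean(diff(cpg)) else len
  c(repetitive_frac = sum(sa$overlap_bp) / len,
    n_genes = nrow(genes),
    gene_total_len = if (nrow(genes)) sum(genes$end - genes$start) else 0,
    n_exons = nrow(exons),
    exon_total_len = if (nrow(exons)) sum(exons$end - exons$start) else 0,
    exon_mean_len = if (nrow(exons)) mean(exons$end - exons$start) else 0,
    n_transcripts = ntx,
    tx_per_gene = if (nrow(genes)) ntx / nrow(genes) else 0,
    island_len = len,
    cpg_pct = 2 * length(cpg) / len,
    cpg_mean_gap = cpg_gap)
}

# windows around an island: exact, +/-400, +/-900 (clipped at 0)
island_windows <- function(rec, radii = c(900L, 400L)) {
  w <- lapply(radii, function(r) c(max(0L, rec$start - r), rec$end + r))
  names(w) <- paste0("w", radii)
  c(w, list(exact = c(rec$start, rec$end)))
}

#' Repeat, Alu-Y and self-alignment features (19)
#'
#' For each of three windows (island +/- 900 bp, +/- 400 bp, and the exact
#' island): repeat count, repeat bp overlap (clipped), repeat fraction of
#' the window, Alu-Y count, Alu-Y bp overlap and self-alignment fraction
#' (18 features); plus the distance from the island midpoint to the
#' nearest Alu-Y element on the chromosome (chromosome length as sentinel
#' when there is none).
#'
#' @param rec A `CpGIslandRecord`.
#' @param bundle An `AnnotationBundle`.
#' @param chrom_len Chromosome length (bp).
#' @return Named numeric vector of 19 features.
#' @export
repeat_features <- function(rec, bundle, chrom_len) {
  wins <- island_windows(rec)
  out <- numeric(0)
  for (wn in names(wins)) {
    w <- wins[[wn]]
    wl <- w[2] - w[1]
    reps <- track_overlaps(bundle$repeats, rec$chrom, w[1], w[2])
    aluy <- reps[grepl("aluy", reps$name, ignore.case = TRUE), , drop = FALSE]
    sa <- track_overlaps(bundle$selfalign, rec$chrom, w[1], w[2])
    v <- c(rep_count = nrow(reps),
           rep_bp = sum(reps$overlap_bp),
           rep_frac = sum(reps$overlap_bp) / wl,
           aluy_count = nrow(aluy),
           aluy_bp = sum(aluy$overlap_bp),
           selfalign_frac = sum(sa$overlap_bp) / wl)
    names(v) <- paste(wn, names(v), sep = "_")
    out <- c(out, v)
  }
  rdf <- bundle$repeats$df
  aluy_all <- rdf[rdf$chrom == rec$chrom &
                    grepl("aluy", rdf$name, ignore.case = TRUE), ,
                  drop = FALSE]
  mid <- island_midpoint(rec)
  d <- if (nrow(aluy_all)) {
    inside <- aluy_all$start <= mid & aluy_all$end > mid
    if (any(inside)) 0 else min(pmin(abs(aluy_all$start - mid),
                                     abs(aluy_all$end - 1L - mid)))
  } else chrom_len
  c(out, aluy_nearest_dist = d)
}

#' SNP features (8)
#'
#' For each window radius (400, 900 bp around the island) and SNP set (all
#' SNPs; T/C SNPs, relevant because bisulfite conversion reads unmethylated
#' C as T): the SNP count inside the window and the distance from the
#' island midpoint to the closest SNP of the set within the window (window
#' radius as sentinel when none is found).
#'
#' @param rec A `CpGIslandRecord`.
#' @param snps SNP `IntervalTrack` (alleles `"X/Y"` in the `name` column).
#' @return Named numeric vector of 8 features.
#' @export
snp_features <- function(rec, snps) {
  mid <- island_midpoint(rec)
  out <- numeric(0)
  for (r in c(400L, 900L)) {
    w <- c(max(0L, rec$start - r), rec$end + r)
    hits <- track_overlaps(snps, rec$chrom, w[1], w[2])
    is_tc <- grepl("^([TC])/([TC])$", hits$name) &
      !grepl("^(T/T|C/C)$", hits$name)
    for (set in c("all", "tc")) {
      sub <- if (set == "all") hits else hits[is_tc, , drop = FALSE]
      d <- if (nrow(sub)) min(abs(sub$start - mid)) else r
      v <- c(nrow(sub), d)
      names(v) <- paste0("w", r, "_", set, c("_count", "_dist"))
      out <- c(out, v)
    }
  }
  out
}
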