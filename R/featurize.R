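#' Assemble the full feature vector per island
#'
#' The reference configuration emits 948 features in 15 classes, in this
#' fixed order (class, width): tss 4, cgi 7, genomic 11, repeat 19, snp 8,
#' periodic 15, closest 6, dinuc 16, tetra 257, flank 4, splice 5,
#' tfbs 457 (456-PFM library + log total hits), structure 43,
#' conservation 4, histone 92 (23 tracks x 4).
#'
#' @name featurize
NULL

#' Canonical feature class names, in schema order
#' @return Character vector of the 15 class names.
#' @export
feature_classes <- function() {
  c("tss", "cgi", "genomic", "repeat", "snp", "periodic", "closest",
    "dinuc", "tetra", "flank", "splice", "tfbs", "structure",
    "conservation", "histone")
}

#' Bundle all resources needed for feature generation
#'
#' @param genome A `GenomeSequence`.
#' @param bundle An `AnnotationBundle` (or `NULL` if annotation classes
#'   are disabled).
#' @param histone_tracks Named list of scored `IntervalTrack`s.
#' @param conservation Scored `IntervalTrack` of conserved elements.
#' @param tfbs_models List of `WeightScoreModel`s (TFBS library).
#' @param splice_models Named list of 4 splice-site `WeightScoreModel`s.
#' @param octamer_table An `OctamerEnergyTable`.
#' @param flank_models Four flanking models from [build_flanking_models()].
#' @return A `FeatureResources` list.
#' @export
feature_resources <- function(genome, bundle = NULL, histone_tracks = NULL,
                              conservation = NULL, tfbs_models = NULL,
                              splice_models = NULL, octamer_table = NULL,
                              flank_models = NULL) {
  structure(list(genome = genome, bundle = bundle,
                 histone_tracks = histone_tracks,
                 conservation = conservation, tfbs_models = tfbs_models,
                 splice_models = splice_models,
                 octamer_table = octamer_table,
                 flank_models = flank_models),
            class = "FeatureResources")
}

# required resource fields per feature class
.class_requirements <- list(
  tss = "bundle", genomic = "bundle", "repeat" = "bundle", snp = "bundle",
  flank = "flank_models", splice = "splice_models", tfbs = "tfbs_models",
  structure = "octamer_table", conservation = "conservation",
  histone = "histone_tracks")

#' Validate that every enabled feature class has its resources
#'
#' @param resources A `FeatureResources`.
#' @param classes Enabled feature classes.
#' @return Invisibly `TRUE`; errors listing all missing resources at once.
#' @export
validate_resources <- function(resources, classes = feature_classes()) {
  missing <- character(0)
  for (cl in classes) {
    req <- .class_requirements[[cl]]
    if (!is.null(req) && is.null(resources[[req]]))
      missing <- c(missing, sprintf("class '%s' needs resource '%s'",
                                    cl, req))
  }
  if (length(missing))
    stop("missing feature resources:\n  ", paste(missing, collapse = "\n  "))
  invisible(TRUE)
}

#' Compute the feature vector of one island record
#'
#' @param rec A `CpGIslandRecord`.
#' @param resources A `FeatureResources`.
#' @param classes Feature classes to compute (subset of
#'   [feature_classes()]); order is always canonical.
#' @return Named numeric vector; names `<class>.<feature>`.
#' @export
island_features <- function(rec, resources, classes = feature_classes()) {
  classes <- intersect(feature_classes(), classes)
  ctx <- sequence_context(rec)
  chrom_len <- resources$genome$lengths[[rec$chrom]]
  out <- list()
  for (cl in classes) {
    v <- switch(cl,
      tss = tss_distance_features(rec, resources$bundle$genes, chrom_len),
      cgi = {
        ex <- track_overlaps(resources$bundle$exons, rec$chrom,
                             rec$start, rec$end)
        cgi_attributes(ctx, coding_overlap = nrow(ex) > 0)
      },
      genomic = genomic_attribute_features(rec, resources$bundle),
      "repeat" = repeat_features(rec, resources$bundle, chrom_len),
      snp = snp_features(rec, resources$bundle$snps),
      periodic = suppressWarnings(periodic_cpg_features(ctx)),
      closest = closest_cpg_features(ctx),
      dinuc = dinucleotide_features(ctx),
      tetra = tetranucleotide_features(ctx),
      flank = flanking_features(rec, resources$flank_models),
      splice = splice_site_features(rec, resources$splice_models),
      tfbs = tfbs_features(rec, resources$tfbs_models),
      structure = dna_structure_features(ctx$seq, resources$octamer_table),
      conservation = conservation_features(rec, resources$conservation),
      histone = histone_features(rec, resources$histone_tracks))
    out[[cl]] <- v
  }
  # unlist() joins the class name and feature name with "."
  unlist(out, use.names = TRUE)
}

#' Compute the feature matrix of a set of islands
#'
#' A special case of the cgi attribute class: the coding flag is 1 when
#' the island overlaps an exon. All islands in one run share one schema.
#'
#' @param records List of `CpGIslandRecord`s.
#' @param resources A `FeatureResources`.
#' @param classes Enabled feature classes.
#' @return A `cgi_features` matrix (rows = islands, ids as rownames) with
#'   the schema attached.
#' @export
featurize <- function(records, resources, classes = feature_classes()) {
  classes <- intersect(feature_classes(), classes)
  validate_resources(resources, classes)
  rows <- lapply(records, island_features, resources = resources,
                 classes = classes)
  nms <- names(rows[[1]])
  if (any(vapply(rows, function(r) !identical(names(r), nms), logical(1))))
    stop("feature schema differs across islands")
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(records, `[[`, character(1), "id")
  # names are "<class>.<rest>"; class is the part before the first dot
  cls <- sub("\\..*$", "", nms)
  feat <- sub("^[^.]*\\.", "", nms)
  schema <- data.frame(class = cls, name = feat, stringsAsFactors = FALSE)
  feature_matrix(mat, schema)
}
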