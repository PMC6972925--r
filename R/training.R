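# Training-set construction: positive/negative labeling from annotation and
# ChIP-Seq tracks, and the stratified four-way split feeding the stack tiers.

#' Label tag clusters as positive or negative training examples
#'
#' Positive: representative closer than 500 bp (strict, strand-agnostic) to
#' an annotated TSS AND the cluster interval overlaps at least one H3K4me3
#' peak AND at least one Pol-II peak.  Negative: the cluster overlaps an
#' intron or exon or lies in intergenic space, and overlaps neither ChIP
#' track.  Clusters in neither category (e.g. TSS-proximal but missing one
#' ChIP mark) are dropped as unlabeled.
#'
#' @param clusters TPM-filtered cluster table.
#' @param tss BED-style table of 1-nt annotated TSS positions.
#' @param h3k4me3,polii ChIP-Seq peak tables.
#' @param exons,introns Annotation tables.
#' @param max_tss_dist Positive-set distance rule (bp, strict), default 500.
#' @return The labeled subset of `clusters` with columns `label`
#'   (`"positive"`/`"negative"`) and `provenance`.
#' @export
label_clusters <- function(clusters, tss, h3k4me3, polii, exons, introns,
                           max_tss_dist = 500L) {
  for (tr in list(tss, h3k4me3, polii, exons, introns))
    if (is.null(tr)) stop("all five annotation/ChIP tracks are required",
                          call. = FALSE)
  if (nrow(clusters) == 0L) {
    clusters$label <- character(0); clusters$provenance <- character(0)
    return(clusters)
  }
  tss_dist <- .nearest_distance(clusters, tss)
  near_tss <- !is.na(tss_dist) & tss_dist < max_tss_dist
  ov_k4 <- .overlaps_any(clusters, h3k4me3)
  ov_pol <- .overlaps_any(clusters, polii)
  ov_exon <- .overlaps_any(clusters, exons)
  ov_intron <- .overlaps_any(clusters, introns)
  intergenic <- !ov_exon & !ov_intron
  positive <- near_tss & ov_k4 & ov_pol
  negative <- !near_tss & !ov_k4 & !ov_pol
  keep <- positive | negative
  out <- clusters[keep, , drop = FALSE]
  out$label <- ifelse(positive[keep], "positive", "negative")
  out$provenance <- ifelse(positive[keep], "tss_proximal_chip_supported",
                           ifelse(ov_intron[keep], "intron",
                                  ifelse(ov_exon[keep], "exon", "intergenic")))
  rownames(out) <- NULL
  out
}

# distance from each cluster representative to the nearest TSS position
.nearest_distance <- function(clusters, tss) {
  if (nrow(tss) == 0L) return(rep(NA_real_, nrow(clusters)))
  vapply(seq_len(nrow(clusters)), function(i) {
    same <- tss[tss$chrom == clusters$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(NA_real_)
    min(abs(same$start - clusters$representative[i]))
  }, numeric(1))
}

#' Split labeled clusters into the four stack-training subsets
#'
#' Stratified by label; subsets are disjoint with union equal to the input.
#' Per class, subset sizes are `round(fraction * n)` with any rounding
#' remainder assigned to the first subset.  Deterministic given `seed`.
#'
#' @param labeled Labeled cluster table from [label_clusters()].
#' @param fractions Four non-negative fractions summing to 1; default
#'   `c(0.50, 0.20, 0.15, 0.15)` (tier-1 SVM/motif set, structural-combiner
#'   set, final-model set, held-out test set).
#' @param seed Integer RNG seed.
#' @return List of four labeled cluster tables.
#' @export
split_four_way <- function(labeled, fractions = c(0.50, 0.20, 0.15, 0.15),
                           seed = 1L) {
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 4 non-negative values summing to 1",
         call. = FALSE)
  classes <- split(seq_len(nrow(labeled)), labeled$label)
  if (length(classes) < 2L || any(lengths(classes) == 0L))
    stop("both classes must be nonempty", call. = FALSE)
  assign <- integer(nrow(labeled))
  set.seed(seed)
  for (idx in classes) {
    n <- length(idx)
    sizes <- round(fractions * n)
    sizes[1] <- n - sum(sizes[-1])
    if (any(sizes <= 0))
      stop("a split fraction yields an empty class subset", call. = FALSE)
    perm <- sample(idx)
    assign[perm] <- rep(1:4, times = sizes)
  }
  out <- lapply(1:4, function(s) {
    sub <- labeled[assign == s, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- c("subset1", "subset2", "subset3", "test")
  out
}

#' Verify that the stack-training subsets are disjoint
#'
#' Data-leak guard used at train time: errors when any cluster (identified
#' by chrom/start/end/strand) appears in more than one subset.
#'
#' @param subsets List of cluster tables.
#' @return `TRUE`, invisibly; errors on overlap.
#' @export
check_tier_isolation <- function(subsets) {
  keys <- lapply(subsets, function(s)
    paste(s$chrom, s$start, s$end, s$strand))
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys))
    stop("training subsets overlap: data leak between stack tiers",
         call. = FALSE)
  invisible(TRUE)
}
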