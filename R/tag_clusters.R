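# CTSS -> expression-filtered tag clusters with representative nucleotides.

#' Aggregate CTSS records into strand-specific tag clusters
#'
#' Single-linkage chaining per (chrom, strand): consecutive CTSS positions
#' closer than `max_gap` bases (strict inequality on the distance) join the
#' same cluster; chaining is transitive, so clusters have no width cap.  Each
#' cluster records its member count sum and the representative nucleotide:
#' the member position with the highest tag count, ties broken by the
#' 5'-most position relative to the strand.
#'
#' @param ctss CTSS table (`chrom`, `pos`, `strand`, `count`), sorted by
#'   chrom then position.
#' @param max_gap Distance threshold in bp (default 50); positions at
#'   distance `< max_gap` are joined.
#' @return Cluster table `data.frame(chrom, start, end, strand, raw_count,
#'   representative, rep_count)`, 0-based half-open, spanning the first to
#'   last member position.
#' @export
cluster_ctss <- function(ctss, max_gap = 50L) {
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  if (nrow(ctss) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), raw_count = integer(),
                      representative = integer(), rep_count = integer()))
  if (any(ctss$count < 1)) stop("CTSS counts must be >= 1", call. = FALSE)
  ord <- order(ctss$chrom, ctss$pos)
  if (!identical(ord, seq_len(nrow(ctss))))
    stop("CTSS input must be sorted by chrom, position", call. = FALSE)
  parts <- split(ctss, paste(ctss$chrom, ctss$strand, sep = "\r"))
  out <- lapply(parts, function(p) {
    gap_break <- c(FALSE, diff(p$pos) >= max_gap)
    cid <- cumsum(gap_break)
    do.call(rbind, lapply(split(p, cid), function(m) {
      rep_pos <- select_representative(m)
      data.frame(chrom = m$chrom[1], start = min(m$pos),
                 end = max(m$pos) + 1L, strand = m$strand[1],
                 raw_count = sum(m$count), representative = rep_pos,
                 rep_count = m$count[match(rep_pos, m$pos)])
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Representative nucleotide of a cluster
#'
#' The member CTSS position with the highest tag count; ties are broken by
#' the 5'-most position relative to the strand (smallest position on `+`,
#' largest on `-`).
#'
#' @param members CTSS table of the cluster members (nonempty, one strand).
#' @return The representative position (0-based integer).
#' @export
select_representative <- function(members) {
  if (nrow(members) == 0L) stop("empty member set", call. = FALSE)
  best <- members[members$count == max(members$count), , drop = FALSE]
  if (members$strand[1] == "-") max(best$pos) else min(best$pos)
}

#' Compute tags-per-million expression for clusters
#'
#' `tpm = raw_count * 1e6 / library_size`.  The library size is the total
#' number of quality-passing 5' tags in the sample.
#'
#' @param clusters Cluster table from [cluster_ctss()].
#' @param library_size Positive total tag count.
#' @return The cluster table with a `tpm` column.
#' @export
normalize_tpm <- function(clusters, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      library_size <= 0)
    stop("library_size must be a single positive number", call. = FALSE)
  clusters$tpm <- clusters$raw_count * 1e6 / library_size
  clusters
}

#' Drop weakly expressed clusters
#'
#' Removes clusters with `tpm < cutoff` (strict drop: a cluster exactly at
#' the cutoff is kept).  Order is preserved.
#'
#' @param clusters Cluster table with a `tpm` column.
#' @param cutoff TPM cutoff, default 0.5.
#' @return Filtered cluster table.
#' @export
filter_by_tpm <- function(clusters, cutoff = 0.5) {
  if (is.null(clusters$tpm)) stop("tpm not computed; run normalize_tpm()",
                                  call. = FALSE)
  out <- clusters[clusters$tpm >= cutoff, , drop = FALSE]
  if (nrow(out) == 0L && nrow(clusters) > 0L)
    warning("all clusters fall below the tpm cutoff", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge nearby tag clusters into unique events
#'
#' Strand-aware merge of clusters whose interval boundaries lie closer than
#' `max_dist` bases (default 1 kb); chaining is transitive.  The merged
#' event's representative is the member representative with the highest tag
#' count (ties: 5'-most, strand-aware).
#'
#' @param clusters Cluster table.
#' @param max_dist Gap threshold in bp, default 1000.
#' @return Merged cluster table with summed `raw_count` (and summed `tpm`
#'   when present).
#' @export
merge_within_distance <- function(clusters, max_dist = 1000L) {
  if (nrow(clusters) == 0L) return(clusters)
  parts <- split(clusters, paste(clusters$chrom, clusters$strand, sep = "\r"))
  out <- lapply(parts, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    gap <- p$start[-1] - cummax(p$end)[-nrow(p)]  # boundary-to-boundary
    cid <- cumsum(c(FALSE, gap >= max_dist))
    do.call(rbind, lapply(split(p, cid), function(m) {
      best <- m[m$rep_count == max(m$rep_count), , drop = FALSE]
      rep_pos <- if (m$strand[1] == "-") max(best$representative) else
        min(best$representative)
      ev <- data.frame(chrom = m$chrom[1], start = min(m$start),
                       end = max(m$end), strand = m$strand[1],
                       raw_count = sum(m$raw_count),
                       representative = rep_pos,
                       rep_count = max(m$rep_count))
      if (!is.null(m$tpm)) ev$tpm <- sum(m$tpm)
      ev
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call expression-filtered CAGE peaks from a CTSS table
#'
#' Convenience wrapper chaining [cluster_ctss()], [normalize_tpm()] and
#' [filter_by_tpm()] with the standard defaults (gap 50 bp, cutoff 0.5 tpm).
#'
#' @param ctss CTSS table.
#' @param max_gap Clustering gap (bp).
#' @param tpm_cutoff Expression cutoff (tags per million).
#' @param library_size Total tags; defaults to `sum(ctss$count)`.
#' @return Filtered cluster table with `tpm`.
#' @export
call_peaks <- function(ctss, max_gap = 50L, tpm_cutoff = 0.5,
                       library_size = sum(ctss$count)) {
  filter_by_tpm(normalize_tpm(cluster_ctss(ctss, max_gap), library_size),
                tpm_cutoff)
}
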