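# Interval utilities.  All coordinates in this package are 0-based,
# half-open [start, end), as in BED; conversion to the 1-based closed
# convention happens only at the GRanges/FASTA boundary.

#' Length of the overlap between two genomic intervals
#'
#' Returns the number of bases shared by two half-open intervals, or 0 when
#' the chromosomes differ or the intervals are disjoint.  Strand is ignored
#' unless `stranded = TRUE`, in which case intervals on different strands
#' never overlap.
#'
#' @param a,b Lists or one-row data frames with elements `chrom`, `start`,
#'   `end` and optionally `strand`.
#' @param stranded Logical; require matching strands?
#' @return Integer overlap length (>= 0).
#' @examples
#' overlap_length(list(chrom = "chr1", start = 0, end = 10),
#'                list(chrom = "chr1", start = 5, end = 20))  # 5
#' @export
overlap_length <- function(a, b, stranded = FALSE) {
  if (a$chrom != b$chrom) return(0L)
  if (stranded && !is.null(a$strand) && !is.null(b$strand) &&
      a$strand != b$strand) return(0L)
  max(0L, as.integer(min(a$end, b$end) - max(a$start, b$start)))
}

# data.frame(chrom,start,end[,strand]) -> GRanges (1-based closed)
.as_granges <- function(df, stranded = FALSE) {
  strand <- if (stranded && !is.null(df$strand)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# indices of rows in `query` overlapping >=1 row of `subject` by >= 1 bp
.overlaps_any <- function(query, subject, stranded = FALSE) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::findOverlaps(
    .as_granges(query, stranded), .as_granges(subject, stranded),
    ignore.strand = !stranded
  )
  seq_len(nrow(query)) %in% S4Vectors::queryHits(hits)
}

.check_intervals <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  if (nrow(df) && any(df$start < 0 | df$end <= df$start))
    stop(what, ": invalid interval (need 0 <= start < end)", call. = FALSE)
  invisible(df)
}
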