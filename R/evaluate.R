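# Benchmark computations: chromatin-state assignment and enrichment,
# ChIP-overlap fractions, hybrid positive/negative zones with ROC and
# gene-level counts, genomic-location priority, and overlap-matching of
# predictions to a reference peak list.

ACTIVE_STATES <- c("TssA", "TssAFlnk", "TxFlnk")

#' Assign each prediction to a chromatin state
#'
#' Each prediction gets the state of the segmentation interval with which it
#' shares the most bases; zero total overlap yields `NA`, and exact ties are
#' broken by the lexicographically first state name.
#'
#' @param predictions Interval table (`chrom`, `start`, `end`).
#' @param states Segmentation table with a `name` column of state mnemonics
#'   (e.g. the 15-state model: TssA, TssAFlnk, ..., Quies).
#' @return Character vector of state names (NA = unassigned).
#' @export
assign_chromatin_state <- function(predictions, states) {
  if (nrow(predictions) == 0L) return(character(0))
  out <- rep(NA_character_, nrow(predictions))
  if (nrow(states) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(.as_granges(predictions),
                                      .as_granges(states),
                                      ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(predictions$end[q], states$end[s]) -
        pmax(predictions$start[q], states$start[s])
  for (i in unique(q)) {
    sel <- q == i
    cand <- data.frame(state = states$name[s[sel]], ov = ov[sel])
    cand <- cand[cand$ov > 0, , drop = FALSE]
    if (!nrow(cand)) next
    best <- cand[cand$ov == max(cand$ov), "state"]
    out[i] <- sort(best)[1]
  }
  out
}

#' Percentages of predictions in active/repressed chromatin
#'
#' Active states are TssA, TssAFlnk and TxFlnk; every other assigned state
#' counts as repressed; predictions overlapping no segmentation interval are
#' `unassigned`.  The three percentages sum to 100.
#'
#' @inheritParams assign_chromatin_state
#' @return Named numeric vector `c(active, repressed, unassigned)` in
#'   percent.
#' @export
state_group_percentages <- function(predictions, states) {
  if (nrow(predictions) == 0L)
    stop("empty prediction set", call. = FALSE)
  st <- assign_chromatin_state(predictions, states)
  n <- length(st)
  c(active = 100 * sum(st %in% ACTIVE_STATES) / n,
    repressed = 100 * sum(!is.na(st) & !st %in% ACTIVE_STATES) / n,
    unassigned = 100 * sum(is.na(st)) / n)
}

#' Log odds ratio for enrichment in a chromatin state
#'
#' `log((a h)(d h) / ((b h)(c h)))` on the 2x2 table (positives in state /
#' not, negatives in state / not); the Haldane correction `h = 0.5` is added
#' to every cell only when some cell is zero.  Natural log.
#'
#' @param a Positives in the state.
#' @param b Positives not in the state.
#' @param c_ Negatives in the state.
#' @param d Negatives not in the state.
#' @return The log odds ratio (finite thanks to the correction).
#' @export
log_odds_enrichment <- function(a, b, c_, d) {
  h <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
  log(((a + h) * (d + h)) / ((b + h) * (c_ + h)))
}

#' Fraction of predictions overlapping at least one peak
#'
#' @param predictions Interval table.
#' @param peaks Peak interval table.
#' @return Percentage in \[0, 100\] of predictions overlapping >= 1 peak by
#'   >= 1 bp.
#' @export
chip_overlap_fraction <- function(predictions, peaks) {
  if (nrow(predictions) == 0L) return(0)
  100 * mean(.overlaps_any(predictions, peaks))
}

#' Hybrid positive/negative zone labels
#'
#' A prediction is `positive_zone` when it overlaps any +/-`pos_half_width`
#' window around an annotated TSS, or when it lies inside a +/-50 kb TSS
#' window and overlaps an H3K4me3 peak (the rescue rule).  It is
#' `negative_zone` when inside a +/-50 kb window with neither condition,
#' and `outside` otherwise (excluded from metrics).
#'
#' @param predictions Interval table.
#' @param tss 1-nt TSS table.
#' @param h3k4me3 H3K4me3 peak table.
#' @param pos_half_width Positive-zone half width (500 or 1000).
#' @param neg_half_width Benchmark-region half width, default 50000.
#' @return Character vector in `{positive_zone, negative_zone, outside}`.
#' @export
hybrid_zone_label <- function(predictions, tss, h3k4me3,
                              pos_half_width = 500L,
                              neg_half_width = 50000L) {
  if (nrow(predictions) == 0L) return(character(0))
  pos_zone <- data.frame(chrom = tss$chrom,
                         start = pmax(0L, tss$start - pos_half_width),
                         end = tss$start + pos_half_width + 1L)
  bench <- data.frame(chrom = tss$chrom,
                      start = pmax(0L, tss$start - neg_half_width),
                      end = tss$start + neg_half_width + 1L)
  in_pos <- .overlaps_any(predictions, pos_zone)
  in_bench <- .overlaps_any(predictions, bench)
  in_k4 <- .overlaps_any(predictions, h3k4me3)
  ifelse(in_pos | (in_bench & in_k4), "positive_zone",
         ifelse(in_bench, "negative_zone", "outside"))
}

#' ROC points and AUC over zone-labeled predictions
#'
#' For each threshold, predictions scoring at or above it are called
#' positive; TPR/FPR are computed over the positive-/negative-zone
#' predictions (`outside` labels are excluded by the caller).  AUC is the
#' trapezoid area over the sorted points, with the (0,0) and (1,1)
#' endpoints included.
#'
#' @param scores Numeric prediction scores.
#' @param positive Logical (or zone labels equal to `"positive_zone"`).
#' @param thresholds Score cutoffs; defaults to all unique scores.
#' @return List with `points` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_points <- function(scores, positive, thresholds = NULL) {
  if (is.character(positive)) positive <- positive == "positive_zone"
  if (is.null(thresholds)) thresholds <- sort(unique(scores))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L)
    stop("need both positive and negative labels for a ROC", call. = FALSE)
  pts <- data.frame(threshold = sort(thresholds, decreasing = TRUE))
  pts$tpr <- vapply(pts$threshold,
                    function(t) sum(scores >= t & positive) / np, numeric(1))
  pts$fpr <- vapply(pts$threshold,
                    function(t) sum(scores >= t & !positive) / nn, numeric(1))
  fpr <- c(0, pts$fpr, 1); tpr <- c(0, pts$tpr, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = pts[, c("threshold", "fpr", "tpr")], auc = auc)
}

#' Gene-level true/false positive counts
#'
#' A gene is a true positive when at least one prediction overlaps its
#' +/-`pos_half_width` TSS window; it is a false positive when it has at
#' least one prediction in its negative zone (+/-`neg_half_width`, outside
#' the positive window) but none in the positive window.  Genes with no
#' predictions count as neither.
#'
#' @param predictions Interval table.
#' @param genes Table with one TSS per gene (`chrom`, `start`, optionally
#'   `name`).
#' @param pos_half_width Positive window half width, default 500.
#' @param neg_half_width Negative window half width, default 50000.
#' @return Named integer vector `c(tp, fp)`.
#' @export
gene_level_counts <- function(predictions, genes, pos_half_width = 500L,
                              neg_half_width = 50000L) {
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pos_win <- data.frame(chrom = g$chrom,
                          start = max(0L, g$start - pos_half_width),
                          end = g$start + pos_half_width + 1L)
    neg_win <- data.frame(chrom = g$chrom,
                          start = max(0L, g$start - neg_half_width),
                          end = g$start + neg_half_width + 1L)
    hit_pos <- any(.overlaps_any(predictions, pos_win))
    hit_neg <- any(.overlaps_any(predictions, neg_win) &
                   !.overlaps_any(predictions, pos_win))
    if (hit_pos) tp <- tp + 1L
    else if (hit_neg) fp <- fp + 1L
  }
  c(tp = tp, fp = fp)
}

#' Assign predictions to genomic location categories by priority
#'
#' First match in the order promoter > exon/intron junction > exon >
#' intron, with a single shared base sufficing; predictions overlapping
#' none are `NA` (discarded from the location tally).
#'
#' @param predictions Interval table.
#' @param promoters,junctions,exons,introns Interval tables (promoters:
#'   1000 bp upstream / 500 bp downstream of each TSS, strand-aware;
#'   junctions: +/-50 bp around splice sites).
#' @return Character vector of categories (NA = none).
#' @export
assign_genomic_location <- function(predictions, promoters, junctions,
                                    exons, introns) {
  n <- nrow(predictions)
  out <- rep(NA_character_, n)
  tracks <- list(promoter = promoters, junction = junctions,
                 exon = exons, intron = introns)
  for (cat in names(tracks)) {
    hit <- .overlaps_any(predictions, tracks[[cat]])
    out[is.na(out) & hit] <- cat
  }
  out
}

#' Strand-aware promoter windows for a gene TSS table
#'
#' 1000 bp upstream and 500 bp downstream of each TSS, with upstream and
#' downstream defined by gene strand.
#'
#' @param genes Table with `chrom`, `start` (TSS position) and `strand`.
#' @param upstream,downstream Window extents in bp.
#' @return Interval table of promoter windows.
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 500L) {
  minus <- !is.null(genes$strand) & genes$strand == "-"
  data.frame(
    chrom = genes$chrom,
    start = pmax(0L, ifelse(minus, genes$start - downstream,
                            genes$start - upstream)),
    end = ifelse(minus, genes$start + upstream + 1L,
                 genes$start + downstream + 1L),
    strand = if (is.null(genes$strand)) "." else genes$strand)
}

#' Match a reference peak list against a prediction set
#'
#' Reference peaks overlapping at least one prediction are positives for
#' that prediction set; the rest are negatives.
#'
#' @param reference_peaks Interval table.
#' @param predictions Interval table.
#' @return Logical vector over the reference peaks.
#' @export
match_to_reference_peaks <- function(reference_peaks, predictions) {
  .overlaps_any(reference_peaks, predictions)
}
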