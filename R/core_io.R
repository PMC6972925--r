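# Readers/writers for the genomic formats the pipeline touches.

#' Extract CAGE tag 5' ends from aligned reads
#'
#' Reads an aligned CAGE sample (BAM or SAM), drops reads below the mapping
#' quality threshold (default 10, inclusive: reads with mapq >= `min_mapq`
#' are kept), takes the 5' end of every remaining alignment (leftmost
#' reference base for `+`, rightmost for `-`) and aggregates counts per
#' (chrom, position, strand).
#'
#' @param path Path to a BAM or SAM file (SAM is converted on the fly).
#' @param min_mapq Minimum mapping quality kept (inclusive); must be >= 0.
#' @return A CTSS table: `data.frame(chrom, pos, strand, count)` with `pos`
#'   0-based, sorted by chrom then position.  The number of unmapped reads
#'   skipped is attached as `attr(, "n_unmapped")` and reported via
#'   `message()`.
#' @export
extract_five_prime_ends <- function(path, min_mapq = 10L) {
  if (!is.numeric(min_mapq) || length(min_mapq) != 1L || min_mapq < 0)
    stop("min_mapq must be a single non-negative number", call. = FALSE)
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  n_total <- Rsamtools::countBam(path)$records
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(mapqFilter = 0,
      what = "mapq",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  n_unmapped <- n_total - length(aln)
  if (n_unmapped > 0)
    message("skipped ", n_unmapped, " unmapped read(s)")
  mapq <- S4Vectors::mcols(aln)$mapq
  keep <- !is.na(mapq) & mapq >= min_mapq
  aln <- aln[keep]
  if (length(aln) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = integer()))
  str <- as.character(BiocGenerics::strand(aln))
  # 5' end: leftmost aligned base on +, rightmost on -; convert to 0-based
  pos1 <- ifelse(str == "+", BiocGenerics::start(aln), BiocGenerics::end(aln))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(aln)),
                   pos = as.integer(pos1 - 1L), strand = str)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   by = df[c("chrom", "pos", "strand")], FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_unmapped") <- n_unmapped
  agg
}

#' Read a CTSS BED file
#'
#' Parses a 6-column BED of single-nucleotide CAGE tag start sites whose
#' score column holds the tag count.
#'
#' @param path Path to a BED6 file; every interval must have width 1 and a
#'   `+`/`-` strand.
#' @return `data.frame(chrom, pos, strand, count)` with 0-based positions.
#' @export
read_ctss_bed <- function(path) {
  if (!file.exists(path)) stop("CTSS BED not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = integer()))
  bed <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character"))
  bad <- which(bed[[3]] - bed[[2]] != 1L)
  if (length(bad))
    stop("CTSS BED line ", bad[1], " has width != 1 (",
         bed[[3]][bad[1]] - bed[[2]][bad[1]], ")", call. = FALSE)
  if (any(!bed[[6]] %in% c("+", "-")))
    stop("CTSS records must have strand '+' or '-'", call. = FALSE)
  cnt <- bed[[5]]
  if (any(cnt < 1 | cnt != round(cnt)))
    stop("CTSS counts must be positive integers", call. = FALSE)
  data.frame(chrom = bed[[1]], pos = bed[[2]], strand = bed[[6]],
             count = as.integer(cnt))
}

#' Write a CTSS table as BED6
#'
#' Inverse of [read_ctss_bed()]: `read_ctss_bed(write_ctss_bed(x, f))` is the
#' identity on valid CTSS tables.
#'
#' @param ctss CTSS table (`chrom`, `pos`, `strand`, `count`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ctss_bed <- function(ctss, path) {
  df <- data.frame(ctss$chrom, ctss$pos, ctss$pos + 1L, "ctss",
                   ctss$count, ctss$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED track into an interval table
#'
#' Generic BED3+ reader for annotation tracks (TSSs, peaks, exons,
#' segmentations).  Column 4, when present, is returned as `name` (used for
#' chromatin-state mnemonics), column 6 as `strand`.
#'
#' @param path BED file path.
#' @return `data.frame(chrom, start, end[, name][, strand])`, 0-based
#'   half-open.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  bed <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  out <- data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]))
  if (ncol(bed) >= 4) out$name <- bed[[4]]
  if (ncol(bed) >= 5) out$score <- suppressWarnings(as.numeric(bed[[5]]))
  if (ncol(bed) >= 6) out$strand <- bed[[6]]
  .check_intervals(out, path)
}

.write_bed <- function(df, path, name = ".", score = 0) {
  n <- nrow(df)
  out <- data.frame(df$chrom, df$start, df$end,
                    if (!is.null(df$name)) df$name else rep(name, n),
                    if (length(score) == n) score else rep(score, n),
                    if (!is.null(df$strand)) df$strand else rep(".", n))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch the sequence window around a position
#'
#' Returns the uppercase sequence of length `2 * half_width + 1` centered on
#' `center` (0-based).  For `-` strand the reverse complement is returned, so
#' windows always read 5' to 3' relative to transcription.  Windows
#' overhanging a chromosome edge are padded with `N` so that every cluster
#' yields a fixed-length window.
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param center 0-based center position (the cluster representative).
#' @param strand `"+"` or `"-"`.
#' @param half_width Half window size in nt.
#' @return A character scalar of length `2 * half_width + 1`.
#' @export
fetch_window_sequence <- function(genome, chrom, center, strand, half_width) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  len <- Biostrings::width(genome[chrom])
  lo <- center - half_width          # 0-based inclusive
  hi <- center + half_width          # 0-based inclusive
  from <- max(0L, lo); to <- min(len - 1L, hi)
  if (from > to) {
    seq <- ""
  } else {
    seq <- as.character(Biostrings::subseq(genome[[chrom]], from + 1L, to + 1L))
  }
  n_left <- from - lo; n_right <- hi - to
  if (n_left > 0 || n_right > 0)
    message("window at ", chrom, ":", center, " padded with ",
            n_left + n_right, " N")
  seq <- paste0(strrep("N", n_left), toupper(seq), strrep("N", n_right))
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

#' Write scored predictions as BED6 plus a full-precision score table
#'
#' The BED score column holds `round(final_score * 1000)` per the BED score
#' convention; the companion `.scores.tsv` keeps full precision for all three
#' branch scores.
#'
#' @param predictions Prediction table from [predict.tss_stack()].
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.scores.tsv`.
#' @return The two paths, invisibly.
#' @export
write_predictions <- function(predictions, prefix) {
  bed <- paste0(prefix, ".bed"); tsv <- paste0(prefix, ".scores.tsv")
  .write_bed(data.frame(chrom = predictions$chrom, start = predictions$start,
                        end = predictions$end,
                        name = sprintf("peak_%d", seq_len(nrow(predictions))),
                        strand = predictions$strand),
             bed, score = round(predictions$final_score * 1000))
  write.table(predictions, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed, tsv))
}
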