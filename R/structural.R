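# Structural-DNA profiles: di-/tri-nucleotide property tables applied to the
# sequence window around each cluster representative, then smoothed.

#' Load a structural property table
#'
#' Reads a TSV whose header line gives the feature name and k (2 or 3),
#' followed by one `kmer<TAB>value` row per k-mer.  The table must be
#' complete: all `4^k` k-mers over ACGT, no duplicates.
#'
#' @param path TSV file.
#' @return A named numeric vector over the `4^k` k-mers, with attributes
#'   `feature` (name) and `k`.
#' @export
load_structural_table <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  if (length(hdr) != 2L) stop("malformed header in ", path, call. = FALSE)
  name <- hdr[1]; k <- as.integer(hdr[2])
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3 in ", path, call. = FALSE)
  rows <- strsplit(lines[-1], "\t")
  kmers <- toupper(vapply(rows, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  if (anyNA(vals))
    stop("non-numeric value for k-mer(s): ",
         paste(kmers[is.na(vals)], collapse = ", "), call. = FALSE)
  all_kmers <- .all_kmers(k)
  dup <- unique(kmers[duplicated(kmers)])
  if (length(dup))
    stop("duplicate k-mer(s) in ", name, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(all_kmers, kmers)
  if (length(missing))
    stop("missing k-mer(s) in ", name, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab <- setNames(vals, kmers)[all_kmers]
  attr(tab, "feature") <- name
  attr(tab, "k") <- k
  tab
}

.all_kmers <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  sort(apply(g, 1, paste, collapse = ""))
}

#' Load the packaged set of 13 structural property tables
#'
#' Eleven dinucleotide scales (duplex disrupt energy, duplex free energy,
#' bending stiffness, denaturation, stacking energy, propeller twist, Z-DNA,
#' A-philicity, protein deformation, B-DNA twist, protein-DNA twist) and two
#' trinucleotide scales (bendability, nucleosome positioning).  The packaged
#' values are representative compilations of the standard published scales
#' used in promoter structural analysis; any complete user table in the same
#' format is accepted in their place.
#'
#' @param dir Directory of TSV tables; defaults to the packaged set.
#' @return Named list of 13 tables (see [load_structural_table()]).
#' @export
default_structural_tables <- function(dir = system.file("extdata",
                                                        "structural",
                                                        package = "cagetss")) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  tabs <- lapply(files, load_structural_table)
  names(tabs) <- vapply(tabs, attr, "", "feature")
  tabs
}

#' Convert a DNA sequence into a raw structural profile
#'
#' `values[i] = table[substr(seq, i, i+k-1)]`; k-mers containing `N` (or any
#' non-ACGT base) are imputed with the table mean so that profile length is
#' a pure function of sequence length.
#'
#' @param seq DNA string (length >= k).
#' @param table Structural table from [load_structural_table()].
#' @return Numeric profile of length `nchar(seq) - k + 1`.
#' @export
sequence_profile <- function(seq, table) {
  k <- attr(table, "k")
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k = ", k, call. = FALSE)
  base <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T")) - 1L
  m <- n - k + 1L
  code <- base[seq_len(m)]
  for (j in seq_len(k - 1L)) code <- code * 4L + base[seq_len(m) + j]
  # sorted ACGT k-mer order coincides with the base-4 code (A=0..T=3)
  vals <- unname(table)[code + 1L]
  vals[is.na(vals)] <- mean(table)
  vals
}

#' Smooth a profile with a centered moving average
#'
#' Valid-mode smoothing: the output drops `(w - 1) / 2` positions at each
#' edge, so a length-n input yields length `n - w + 1`.
#'
#' @param profile Numeric vector.
#' @param w Odd window width, `1 <= w <= length(profile)`.
#' @return Smoothed profile.
#' @export
smooth_profile <- function(profile, w) {
  if (w %% 2 == 0) stop("smoothing window w must be odd", call. = FALSE)
  if (w > length(profile))
    stop("smoothing window longer than profile", call. = FALSE)
  if (w == 1L) return(profile)
  sm <- stats::filter(profile, rep(1 / w, w), sides = 2)
  as.numeric(sm[!is.na(sm)])
}

#' Structural feature vectors for one cluster
#'
#' For each property table: fetch the strand-aware window around the
#' representative, convert it to a raw profile and smooth it.  Vector
#' lengths are fixed per feature given the window configuration.
#'
#' @param genome `DNAStringSet`.
#' @param cluster One-row cluster (needs `chrom`, `representative`,
#'   `strand`).
#' @param tables List of structural tables.
#' @param half_width Window half-width in nt (window is `2*half_width+1`).
#' @param w Smoothing window (odd).
#' @return Named list of numeric vectors, one per feature.
#' @export
structural_vector <- function(genome, cluster, tables, half_width = 500L,
                              w = 11L) {
  seq <- fetch_window_sequence(genome, cluster$chrom, cluster$representative,
                               cluster$strand, half_width)
  lapply(tables, function(tab) smooth_profile(sequence_profile(seq, tab), w))
}

# matrix of smoothed profiles for many clusters under one table
.structural_matrix <- function(genome, clusters, table, half_width, w) {
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    seq <- suppressMessages(
      fetch_window_sequence(genome, cl$chrom, cl$representative, cl$strand,
                            half_width))
    smooth_profile(sequence_profile(seq, table), w)
  })
  do.call(rbind, rows)
}
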