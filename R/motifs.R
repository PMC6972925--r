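# Polymerase II core-promoter motifs: JASPAR PFMs converted to TRAP-style
# mismatch-energy models, scored as expected occupancy over a 100-bp window.

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the JASPAR 2016+ layout: a `>ID name` header followed by four
#' rows `A [ 1 2 3 ]` ... `T [ ... ]` (bare space-separated rows are also
#' accepted, in A, C, G, T order).
#'
#' @param path JASPAR-format file.
#' @return Named list of 4 x W count matrices (rows A, C, G, T); names are
#'   the motif names (or IDs when no name is given).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motifs found in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(toks) >= 2) paste(toks[-1], collapse = " ") else toks[1]
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4L) stop("motif ", name, ": missing base row(s)",
                                call. = FALSE)
    body <- body[1:4]
    labelled <- grepl("^[ACGTacgt]", body)
    rows <- lapply(body, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    if (all(labelled)) {
      bases <- toupper(substr(body, 1, 1))
      if (!setequal(bases, c("A", "C", "G", "T")))
        stop("motif ", name, ": missing base row(s)", call. = FALSE)
      rows <- rows[match(c("A", "C", "G", "T"), bases)]
    }
    wl <- lengths(rows)
    if (length(unique(wl)) != 1L)
      stop("motif ", name, ": rows of unequal width", call. = FALSE)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(colSums(m) == 0)) stop("motif ", name, ": all-zero column",
                                   call. = FALSE)
    out[[name]] <- m
  }
  out
}

#' The packaged set of 13 Pol-II core-promoter motif matrices
#'
#' Inr, TATA-box, MTE, GC-Box, CCAAT-Box, DPE, BREu, BREd, DCE-S-I/II/III,
#' XCPE1 and MED1.  The packaged matrices are synthetic stand-ins built from
#' the published IUPAC consensus of each element (see
#' `inst/extdata/motifs/pol2_core_motifs_synthetic.jaspar`); point `path` at
#' real JASPAR matrices to use curated profiles.
#'
#' @param path JASPAR-format file; defaults to the packaged set.
#' @return Named list of count matrices in the fixed motif order above.
#' @export
default_motif_pfms <- function(path = system.file(
    "extdata", "motifs", "pol2_core_motifs_synthetic.jaspar",
    package = "cagetss")) {
  read_jaspar_pfm(path)
}

#' Convert a count matrix to a TRAP mismatch-energy model
#'
#' Per column j: `E[b, j] = (1/lambda) * log((max_b' c[b', j] + p) /
#' (c[b, j] + p))`, so the per-column consensus base has energy exactly 0
#' and all energies are >= 0.  `ln_R0` defaults to `0.584 * W - 5.66`.
#'
#' @param counts 4 x W count matrix (rows A, C, G, T).
#' @param lambda TRAP scaling parameter (> 0), default 0.7.
#' @param pseudocount Added to every count (> 0), default 1.
#' @param ln_r0 Log of the TRAP R0 parameter; default `0.584 * W - 5.66`.
#' @param motif_id Stored identifier.
#' @return List with `motif_id`, `energy` (4 x W), `lambda`, `ln_r0`,
#'   `width`.
#' @export
build_energy_model <- function(counts, lambda = 0.7, pseudocount = 1,
                               ln_r0 = NULL, motif_id = "motif") {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  W <- ncol(counts)
  cm <- counts + pseudocount
  energy <- sweep(-log(cm), 2, log(apply(cm, 2, max)), `+`) / lambda
  if (is.null(ln_r0)) ln_r0 <- 0.584 * W - 5.66
  list(motif_id = motif_id, energy = energy, lambda = lambda,
       ln_r0 = ln_r0, width = W)
}

#' TRAP binding affinity of a sequence for one motif
#'
#' Expected occupancy summed over every offset on both strands:
#' `sum_i R0 * exp(-E_i) / (1 + R0 * exp(-E_i))` where `E_i` is the summed
#' mismatch energy of the window starting at offset i.  Windows containing
#' `N` contribute 0.  A sequence shorter than the motif yields 0 with a
#' warning.
#'
#' @param seq DNA string.
#' @param model Energy model from [build_energy_model()].
#' @return Non-negative affinity.
#' @export
trap_affinity <- function(seq, model) {
  W <- model$width
  if (nchar(seq) < W) {
    warning("sequence shorter than motif width; affinity 0", call. = FALSE)
    return(0)
  }
  fwd <- .strand_energy(seq, model)
  rev <- .strand_energy(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))), model)
  e <- c(fwd, rev)
  e <- e[is.finite(e)]
  if (!length(e)) return(0)
  x <- exp(model$ln_r0 - e)
  sum(x / (1 + x))
}

# per-offset window energies on one strand; Inf where the window contains N
.strand_energy <- function(seq, model) {
  base <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  n <- length(base); W <- model$width
  m <- n - W + 1L
  e <- numeric(m)
  for (j in seq_len(W)) {
    bj <- base[seq_len(m) + j - 1L]
    ej <- model$energy[, j][bj]          # NA for N
    e <- e + ej
  }
  e[is.na(e)] <- Inf
  e
}

#' Motif affinity vector for one cluster
#'
#' TRAP affinities of the 13 Pol-II motifs over the strand-aware window
#' centered on the cluster representative (default +/-50 nt, the 100-bp
#' motif window).  Vector order follows the fixed motif list of the model
#' set.
#'
#' @param genome `DNAStringSet`.
#' @param cluster One-row cluster table.
#' @param models Named list of energy models.
#' @param half_width Window half-width (default 50).
#' @return Named numeric vector, one affinity per motif.
#' @export
motif_vector <- function(genome, cluster, models, half_width = 50L) {
  seq <- suppressMessages(
    fetch_window_sequence(genome, cluster$chrom, cluster$representative,
                          cluster$strand, half_width))
  vapply(models, function(m) trap_affinity(seq, m), numeric(1))
}

# affinity matrix for many clusters (rows) x motifs (cols)
.motif_matrix <- function(genome, clusters, models, half_width) {
  t(vapply(seq_len(nrow(clusters)),
           function(i) motif_vector(genome, clusters[i, ], models, half_width),
           numeric(length(models))))
}

# energy models for a PFM list with shared TRAP parameters
.build_models <- function(pfms, lambda = 0.7, pseudocount = 1) {
  out <- lapply(names(pfms), function(nm)
    build_energy_model(pfms[[nm]], lambda = lambda, pseudocount = pseudocount,
                       motif_id = nm))
  names(out) <- names(pfms)
  out
}
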