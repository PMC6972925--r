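# Self-contained synthetic benchmark: a random genome with planted
# promoters (core-promoter motifs + an AT-rich upstream block), CAGE 5'-end
# pileups at the planted TSSs plus dispersed noise clusters, and matching
# annotation / ChIP / chromatin-state truth tracks.

#' Configuration for the synthetic CAGE benchmark
#'
#' Defaults emulate a small but complete study: a 1-Mb genome, 200 planted
#' promoters at least 2 kb apart, 300 noise clusters placed away from any
#' true TSS, Poisson(50) tags per true TSS with 2-nt positional jitter and
#' Poisson(10) tags per noise cluster over a wider (10-nt) dispersion -
#' both classes comfortably pass the 0.5-tpm filter.
#'
#' @param genome_length Genome size in bp.
#' @param n_promoters Number of planted promoters.
#' @param n_noise_clusters Number of planted noise clusters.
#' @param gc_background Background GC fraction.
#' @param tags_per_true_tss Poisson mean of tags at a true TSS.
#' @param tags_per_noise_cluster Poisson mean of tags at a noise cluster.
#' @param positional_jitter_sd SD (nt) of tag positions around a true TSS.
#' @param noise_dispersion_sd SD (nt) of tag positions around a noise
#'   cluster center.
#' @param plant_motifs Plant TATA/Inr consensus at canonical offsets
#'   (TATA at -31, Inr across the TSS)?  Disable for motif ablations.
#' @param at_block Plant the AT-rich upstream block (-150..-1, GC 0.25)
#'   that creates the structural-profile contrast?  Disable for structural
#'   ablations.
#' @param chip_fn_rate False-negative rate of the simulated ChIP peak
#'   tracks (fraction of true TSSs without a peak).
#' @return A list of class `sim_config`.
#' @export
simulate_config <- function(genome_length = 1e6L, n_promoters = 200L,
                            n_noise_clusters = 300L, gc_background = 0.41,
                            tags_per_true_tss = 50,
                            tags_per_noise_cluster = 10,
                            positional_jitter_sd = 2,
                            noise_dispersion_sd = 10,
                            plant_motifs = TRUE, at_block = TRUE,
                            chip_fn_rate = 0) {
  cfg <- as.list(environment())
  if (any(c(genome_length, n_promoters, n_noise_clusters) <= 0))
    stop("sizes must be positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

.sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.sample_from_pfm <- function(pfm) {
  paste(vapply(seq_len(ncol(pfm)), function(j)
    sample(rownames(pfm), 1, prob = pfm[, j] / sum(pfm[, j])), ""),
    collapse = "")
}

#' Generate the synthetic genome with planted promoters
#'
#' Background bases are i.i.d. at the configured GC.  Each promoter gets
#' (strand-aware, 5'->3' relative to transcription) an AT-rich block at
#' -150..-1, a TATA-box sampled from the packaged TATA PFM at -31 and an
#' Inr sampled from the packaged Inr PFM across the TSS.  Promoters are
#' placed >= 2 kb apart.
#'
#' @param config [simulate_config()].
#' @param seed RNG seed.
#' @return List: `genome` (`DNAStringSet`, one chromosome "chrS"),
#'   `promoters` (`data.frame(chrom, tss, strand)`).
#' @export
generate_genome <- function(config, seed = 1L) {
  set.seed(seed)
  L <- as.integer(config$genome_length)
  bases <- .sample_bases(L, config$gc_background)
  margin <- 3000L; minsep <- 2000L
  n <- config$n_promoters
  span <- L - 2L * margin - (n - 1L) * minsep
  if (span <= n) stop("genome too short for the requested promoters",
                      call. = FALSE)
  draw <- sort(sample.int(span, n))
  tss <- margin + draw + (seq_len(n) - 1L) * minsep
  strand <- sample(c("+", "-"), n, replace = TRUE)
  pfms <- default_motif_pfms()
  for (i in seq_len(n)) {
    cassette <- .sample_bases(201L, if (config$at_block) 0.25 else
      config$gc_background)                      # local coords -150..+50
    cassette[151:201] <- .sample_bases(51L, config$gc_background)
    if (config$plant_motifs) {
      tata <- strsplit(.sample_from_pfm(pfms[["TATA-box"]]), "")[[1]]
      cassette[(151 - 31):(151 - 31 + length(tata) - 1)] <- tata
      inr <- strsplit(.sample_from_pfm(pfms[["Inr"]]), "")[[1]]
      cassette[(151 - 3):(151 - 3 + length(inr) - 1)] <- inr
      cassette[151] <- "A"                       # Inr adenine on the TSS
    }
    if (strand[i] == "+") {
      idx <- (tss[i] - 150L):(tss[i] + 50L) + 1L
      bases[idx] <- cassette
    } else {
      rc <- rev(chartr("ACGT", "TGCA", cassette))
      idx <- (tss[i] - 50L):(tss[i] + 150L) + 1L
      bases[idx] <- rc
    }
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chrS"
  list(genome = genome,
       promoters = data.frame(chrom = "chrS", tss = tss, strand = strand))
}

#' Simulate CTSS records for the synthetic sample
#'
#' Per true TSS a Poisson tag total spread by rounded Gaussian jitter; per
#' noise cluster a random center (>= 1.5 kb from any true TSS, >= 500 bp
#' from other noise centers) with a wider Gaussian spread and uniform
#' random strand.  Zero-tag sites simply emit no records.
#'
#' @param config [simulate_config()].
#' @param promoters Promoter table from [generate_genome()].
#' @param seed RNG seed.
#' @return List: `ctss` table, `library_size`, `noise_centers`.
#' @export
simulate_ctss <- function(config, promoters, seed = 2L) {
  set.seed(seed)
  L <- as.integer(config$genome_length)
  pos <- integer(0); str <- character(0)
  for (i in seq_len(nrow(promoters))) {
    n <- rpois(1, config$tags_per_true_tss)
    if (n == 0) next
    p <- promoters$tss[i] + round(rnorm(n, 0, config$positional_jitter_sd))
    pos <- c(pos, pmin(pmax(p, 0L), L - 1L))
    str <- c(str, rep(promoters$strand[i], n))
  }
  centers <- integer(0)
  guard <- 0L
  while (length(centers) < config$n_noise_clusters && guard < 1e6L) {
    cand <- sample.int(L, 1L) - 1L
    guard <- guard + 1L
    if (any(abs(cand - promoters$tss) < 1500L)) next
    if (length(centers) && any(abs(cand - centers) < 500L)) next
    centers <- c(centers, cand)
  }
  for (cen in centers) {
    n <- rpois(1, config$tags_per_noise_cluster)
    if (n == 0) next
    p <- cen + round(rnorm(n, 0, config$noise_dispersion_sd))
    pos <- c(pos, pmin(pmax(p, 0L), L - 1L))
    str <- c(str, rep(sample(c("+", "-"), 1), n))
  }
  df <- data.frame(chrom = "chrS", pos = as.integer(pos), strand = str)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   by = df[c("chrom", "pos", "strand")], FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  list(ctss = agg, library_size = sum(agg$count),
       noise_centers = sort(centers))
}

#' Emit annotation, ChIP and chromatin-state truth tracks
#'
#' H3K4me3 and Pol-II peaks are +/-500 bp blocks at each true TSS (subject
#' to the configured false-negative rate); the segmentation marks TssA over
#' the same blocks and Quies everywhere else (a gap-free, non-overlapping
#' partition).  Each promoter also gets a strand-aware 1.5-kb gene body
#' tiled with exons and introns downstream of the TSS.
#'
#' @param config [simulate_config()].
#' @param promoters Promoter table.
#' @param seed RNG seed (used only when `chip_fn_rate > 0`).
#' @return List of interval tables: `tss`, `h3k4me3`, `polii`, `exons`,
#'   `introns`, `states`, `genes`.
#' @export
emit_truth_tracks <- function(config, promoters, seed = 3L) {
  set.seed(seed)
  L <- as.integer(config$genome_length)
  tss <- data.frame(chrom = promoters$chrom, start = promoters$tss,
                    end = promoters$tss + 1L, name = sprintf(
                      "gene_%03d", seq_len(nrow(promoters))),
                    strand = promoters$strand)
  peak <- data.frame(chrom = promoters$chrom,
                     start = pmax(0L, promoters$tss - 500L),
                     end = pmin(L, promoters$tss + 501L))
  keep_k4 <- runif(nrow(peak)) >= config$chip_fn_rate
  keep_pol <- runif(nrow(peak)) >= config$chip_fn_rate
  # exon/intron tiling of a 1.5-kb gene body downstream of the TSS
  body <- list(exon = rbind(c(0L, 200L), c(700L, 900L), c(1400L, 1500L)),
               intron = rbind(c(200L, 700L), c(900L, 1400L)))
  mk_body <- function(kind) {
    do.call(rbind, lapply(seq_len(nrow(promoters)), function(i) {
      t0 <- promoters$tss[i]; minus <- promoters$strand[i] == "-"
      seg <- body[[kind]]
      start <- if (minus) t0 - seg[, 2] else t0 + seg[, 1]
      end <- if (minus) t0 - seg[, 1] else t0 + seg[, 2]
      data.frame(chrom = promoters$chrom[i],
                 start = pmax(0L, start), end = pmin(L, end),
                 strand = promoters$strand[i])
    }))
  }
  # gap-free segmentation: TssA on the +/-500 promoter blocks, Quies between
  blocks <- peak[order(peak$start), ]
  bound <- sort(unique(c(0L, blocks$start, blocks$end, L)))
  seg <- data.frame(chrom = "chrS", start = head(bound, -1),
                    end = tail(bound, -1))
  in_tssa <- vapply(seq_len(nrow(seg)), function(i)
    any(blocks$start <= seg$start[i] & seg$end[i] <= blocks$end),
    logical(1))
  seg$name <- ifelse(in_tssa, "TssA", "Quies")
  list(tss = tss,
       h3k4me3 = peak[keep_k4, , drop = FALSE],
       polii = peak[keep_pol, , drop = FALSE],
       exons = mk_body("exon"), introns = mk_body("intron"),
       states = seg, genes = tss)
}

#' Generate the full synthetic benchmark
#'
#' Runs [generate_genome()], [simulate_ctss()] and [emit_truth_tracks()]
#' under one seed and optionally writes everything (FASTA, CTSS BED, truth
#' BEDs, promoter table) into a directory.
#'
#' @param config [simulate_config()].
#' @param seed Run seed; the three stages use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param dir Optional output directory.
#' @return List: `genome`, `promoters`, `ctss`, `library_size`,
#'   `noise_centers`, `tracks`.
#' @export
simulate_cage_benchmark <- function(config = simulate_config(), seed = 1L,
                                    dir = NULL) {
  gen <- generate_genome(config, seed = seed)
  sim <- simulate_ctss(config, gen$promoters, seed = seed + 1L)
  tracks <- emit_truth_tracks(config, gen$promoters, seed = seed + 2L)
  out <- list(genome = gen$genome, promoters = gen$promoters,
              ctss = sim$ctss, library_size = sim$library_size,
              noise_centers = sim$noise_centers, tracks = tracks)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(gen$genome, file.path(dir, "genome.fa"))
    write_ctss_bed(sim$ctss, file.path(dir, "ctss.bed"))
    for (nm in names(tracks))
      .write_bed(tracks[[nm]], file.path(dir, paste0(nm, ".bed")))
    write.table(gen$promoters, file.path(dir, "promoters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Truth labels for clusters of a synthetic sample
#'
#' A cluster is a true-TSS event when its representative lies within
#' `max_dist` of a planted TSS (matching the planted strand), otherwise it
#' is a noise event.
#'
#' @param clusters Cluster table.
#' @param promoters Promoter table from the generator.
#' @param max_dist Matching distance (bp), default 500.
#' @return Logical vector (TRUE = true TSS).
#' @export
truth_labels <- function(clusters, promoters, max_dist = 500L) {
  vapply(seq_len(nrow(clusters)), function(i) {
    same <- promoters[promoters$strand == clusters$strand[i], , drop = FALSE]
    any(abs(same$tss - clusters$representative[i]) <= max_dist)
  }, logical(1))
}
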