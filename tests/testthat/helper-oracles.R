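# Independent oracles and shared fixtures.  The oracles deliberately use a
# different construction than the package code paths they check.

# Brute-force single-linkage clustering: connected components of the graph
# joining any two CTSS positions (same chrom & strand) at distance < max_gap.
bf_cluster <- function(ctss, max_gap) {
  n <- nrow(ctss)
  if (n == 0L) return(ctss[0, ])
  adj <- outer(ctss$chrom, ctss$chrom, "==") &
    outer(ctss$strand, ctss$strand, "==") &
    abs(outer(ctss$pos, ctss$pos, "-")) < max_gap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    m <- ctss[idx, , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$pos), end = max(m$pos) + 1L,
               strand = m$strand[1], raw_count = sum(m$count))
  }))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_ctss <- function(n, max_pos = 1000L, chroms = c("c1", "c2")) {
  df <- data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    count = sample.int(20L, n, replace = TRUE))
  df <- df[!duplicated(df[c("chrom", "pos", "strand")]), , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Naive TRAP: explicit loops over every offset and both strands.
bf_trap <- function(seq, model) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  one_strand <- function(s) {
    W <- model$width
    total <- 0
    for (i in seq_len(nchar(s) - W + 1L)) {
      win <- substr(s, i, i + W - 1L)
      bases <- strsplit(win, "")[[1]]
      if (any(!bases %in% c("A", "C", "G", "T"))) next
      E <- 0
      for (j in seq_len(W))
        E <- E + model$energy[bases[j], j]
      x <- exp(model$ln_r0) * exp(-E)
      total <- total + x / (1 + x)
    }
    total
  }
  as.numeric(one_strand(seq) + one_strand(rc(seq)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_pfm <- function(W) {
  m <- matrix(sample(0:20, 4L * W, replace = TRUE), 4, W,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  zero <- colSums(m) == 0
  m[1, zero] <- 1L
  m
}

# small structural table builders
tiny_table <- function(values, name = "toy", k = 2L) {
  kmers <- cagetss:::.all_kmers(k)
  tab <- stats::setNames(values[seq_along(kmers)], kmers)
  attr(tab, "feature") <- name; attr(tab, "k") <- k
  tab
}

toy_genome <- function(seq, chrom = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

# fast configuration for machinery tests (not the benchmark conditions)
fast_config <- function(...) {
  tss_config(struct_half_width = 40L, smooth_w = 5L,
             svm_cost_grid = 2^c(0, 6), svm_gamma_grid = 2^c(-6, -2),
             cv_folds = 5L, sgb_tune_iters = 5L, sgb_cv_repeats = 2L, ...)
}

# one small fitted stack shared across test files (built on first use)
.fixture_env <- new.env(parent = emptyenv())
get_tiny_stack <- function() {
  if (!is.null(.fixture_env$stack)) return(.fixture_env$stack)
  cfg <- simulate_config(genome_length = 2e5, n_promoters = 35,
                         n_noise_clusters = 45)
  bench <- simulate_cage_benchmark(cfg, seed = 401L)
  clusters <- call_peaks(bench$ctss)
  labeled <- label_clusters(clusters, bench$tracks$tss,
                            bench$tracks$h3k4me3, bench$tracks$polii,
                            bench$tracks$exons, bench$tracks$introns)
  stack <- fit_tss_stack(labeled, bench$genome, fast_config(), seed = 7L)
  .fixture_env$stack <- stack
  .fixture_env$bench <- bench
  .fixture_env$clusters <- clusters
  stack
}
get_tiny_bench <- function() { get_tiny_stack(); .fixture_env$bench }
get_tiny_clusters <- function() { get_tiny_stack(); .fixture_env$clusters }
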