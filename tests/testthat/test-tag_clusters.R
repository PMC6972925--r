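# Clustering, expression normalization/filtering, representatives, merging.

test_that("single-linkage chaining joins positions closer than the gap", {
  ctss <- data.frame(chrom = "c1", pos = c(100L, 130L, 200L),
                     strand = "+", count = c(3L, 2L, 1L))
  cl <- cluster_ctss(ctss, max_gap = 50)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(100L, 200L))
  expect_equal(cl$end, c(131L, 201L))
  expect_equal(cl$raw_count, c(5L, 1L))
  # gap exactly equal to max_gap splits (strict "closer than")
  cl2 <- cluster_ctss(data.frame(chrom = "c1", pos = c(0L, 50L),
                                 strand = "+", count = c(1L, 1L)), 50)
  expect_equal(nrow(cl2), 2L)
  # identical positions on opposite strands stay separate
  both <- data.frame(chrom = "c1", pos = c(10L, 10L),
                     strand = c("+", "-"), count = c(2L, 3L))
  expect_equal(nrow(cluster_ctss(both, 50)), 2L)
  # one record -> width-1 cluster
  one <- cluster_ctss(data.frame(chrom = "c1", pos = 7L, strand = "-",
                                 count = 4L), 50)
  expect_equal(one$end - one$start, 1L)
  expect_equal(one$raw_count, 4L)
  expect_error(cluster_ctss(ctss[c(2, 1, 3), ], 50), "sorted")
  expect_equal(nrow(cluster_ctss(ctss[0, ], 50)), 0L)
})

test_that("clustering equals brute-force connected components", {
  for (seed in 1:60) {
    set.seed(seed)
    ctss <- random_ctss(sample(2:40, 1), max_pos = 400L)
    gap <- sample(c(1L, 5L, 20L, 50L), 1)
    got <- cluster_ctss(ctss, gap)
    want <- bf_cluster(ctss, gap)
    expect_equal(got[names(want)], want, ignore_attr = TRUE)
  }
})

test_that("count conservation and gap monotonicity hold", {
  for (seed in 1:25) {
    set.seed(seed + 100)
    ctss <- random_ctss(sample(5:80, 1))
    gaps <- c(1L, 10L, 30L, 80L, 200L)
    ns <- vapply(gaps, function(g) nrow(cluster_ctss(ctss, g)), integer(1))
    expect_true(all(diff(ns) <= 0))    # larger gap, never more clusters
    cl <- cluster_ctss(ctss, 30L)
    expect_equal(sum(cl$raw_count), sum(ctss$count))
    # representative is always a member CTSS position on its strand
    for (i in seq_len(nrow(cl))) {
      members <- ctss$pos[ctss$chrom == cl$chrom[i] &
                          ctss$strand == cl$strand[i] &
                          ctss$pos >= cl$start[i] & ctss$pos < cl$end[i]]
      expect_true(cl$representative[i] %in% members)
    }
  }
})

test_that("tpm arithmetic and filtering boundaries", {
  cl <- data.frame(chrom = "c", start = c(0L, 10L, 20L),
                   end = c(1L, 11L, 21L), strand = "+",
                   raw_count = c(1L, 50L, 3L),
                   representative = c(0L, 10L, 20L),
                   rep_count = c(1L, 50L, 3L))
  expect_equal(normalize_tpm(cl, 1e6)$tpm[1], 1.0)
  expect_equal(normalize_tpm(cl, 2e7)$tpm[2], 2.5)
  expect_error(normalize_tpm(cl, 0), "positive")
  cl$tpm <- c(0.4, 0.5, 0.6)
  kept <- filter_by_tpm(cl, 0.5)
  expect_equal(kept$tpm, c(0.5, 0.6))  # inclusive keep at the cutoff
  expect_equal(filter_by_tpm(cl, 0), cl, ignore_attr = TRUE)
  expect_warning(out <- filter_by_tpm(cl, 10), "below")
  expect_equal(nrow(out), 0L)
})

test_that("representative selection is argmax with 5'-most tie-break", {
  m <- data.frame(chrom = "c", pos = c(100L, 101L, 102L), strand = "+",
                  count = c(3L, 5L, 2L))
  expect_equal(select_representative(m), 101L)
  tie <- data.frame(chrom = "c", pos = c(100L, 105L), strand = "+",
                    count = c(4L, 4L))
  expect_equal(select_representative(tie), 100L)
  tie$strand <- "-"
  expect_equal(select_representative(tie), 105L)
  expect_equal(select_representative(m[2, ]), 101L)
  expect_error(select_representative(m[0, ]), "empty")
})

test_that("1-kb merge is strand-aware, transitive, boundary-to-boundary", {
  mk <- function(start, end, strand, rep, repc = 5L)
    data.frame(chrom = "c", start = start, end = end, strand = strand,
               raw_count = repc, representative = rep, rep_count = repc)
  two <- rbind(mk(0L, 100L, "+", 50L), mk(500L, 600L, "+", 550L))
  expect_equal(nrow(merge_within_distance(two, 1000L)), 1L)   # gap 400
  opp <- rbind(mk(0L, 100L, "+", 50L), mk(200L, 300L, "-", 250L))
  expect_equal(nrow(merge_within_distance(opp, 1000L)), 2L)   # strandness
  chain <- rbind(mk(0L, 100L, "+", 50L, 3L), mk(1000L, 1100L, "+", 1050L, 9L),
                 mk(2000L, 2100L, "+", 2050L, 4L))
  merged <- merge_within_distance(chain, 1000L)
  expect_equal(nrow(merged), 1L)                              # transitive
  expect_equal(merged$representative, 1050L)   # highest-coverage member rep
  expect_equal(merged$raw_count, 16L)
  # gap exactly 1000 does not merge
  apart <- rbind(mk(0L, 100L, "+", 50L), mk(1100L, 1200L, "+", 1150L))
  expect_equal(nrow(merge_within_distance(apart, 1000L)), 2L)
})

test_that("call_peaks chains clustering, normalization and filtering", {
  ctss <- data.frame(chrom = "c1", pos = c(10L, 20L, 500L), strand = "+",
                     count = c(30L, 30L, 1L))
  peaks <- call_peaks(ctss, max_gap = 50, tpm_cutoff = 2e4)
  expect_equal(nrow(peaks), 1L)        # the singleton fails 20000 tpm
  expect_equal(peaks$raw_count, 60L)
  expect_equal(peaks$tpm, 60 / 61 * 1e6)
})
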