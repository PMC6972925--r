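# Benchmark arithmetic: state assignment, enrichment, zones, ROC, locations.

iv <- function(start, end, chrom = "c1", ...)
  data.frame(chrom = chrom, start = start, end = end, ...)

test_that("chromatin-state assignment picks the largest overlap", {
  states <- rbind(iv(0L, 130L, name = "TssA"),
                  iv(130L, 1000L, name = "Quies"))
  # 30 bp in TssA, 70 bp in Quies
  expect_equal(assign_chromatin_state(iv(100L, 200L), states), "Quies")
  # zero overlap -> NA
  expect_true(is.na(assign_chromatin_state(iv(5000L, 5100L), states)))
  # exact tie -> lexicographically first state name
  tie <- rbind(iv(0L, 50L, name = "TxFlnk"), iv(50L, 100L, name = "Quies"))
  expect_equal(assign_chromatin_state(iv(25L, 75L), tie), "Quies")
})

test_that("state-group percentages partition the prediction set", {
  states <- rbind(iv(0L, 1000L, name = "TssA"),
                  iv(1000L, 2000L, name = "Quies"))
  preds <- rbind(iv(seq(0, 700, 100), seq(0, 700, 100) + 50L),  # 8 active
                 iv(1500L, 1550L),                              # 1 repressed
                 iv(9000L, 9050L))                              # 1 unassigned
  pct <- state_group_percentages(preds, states)
  expect_equal(unname(pct), c(80, 10, 10))
  expect_equal(sum(pct), 100)
  all_active <- state_group_percentages(iv(10L, 20L), states)
  expect_equal(unname(all_active), c(100, 0, 0))
  expect_error(state_group_percentages(iv(1L, 2L)[0, ], states), "empty")
})

test_that("log odds enrichment with conditional Haldane correction", {
  expect_equal(log_odds_enrichment(90, 10, 50, 50), log(9))
  expect_equal(log_odds_enrichment(50, 50, 50, 50), 0)
  v <- log_odds_enrichment(10, 0, 5, 5)
  expect_true(is.finite(v))
  expect_equal(v, log((10.5 * 5.5) / (0.5 * 5.5)))
})

test_that("ChIP overlap fraction counts >= 1 bp overlaps", {
  preds <- iv(c(0L, 100L, 200L, 300L), c(50L, 150L, 250L, 350L))
  peaks <- iv(c(40L, 120L, 340L), c(60L, 130L, 360L))
  expect_equal(chip_overlap_fraction(preds, peaks), 75)
  expect_equal(chip_overlap_fraction(preds, peaks[0, ]), 0)
  # end-to-start touching is a 0-bp overlap under half-open coordinates
  expect_equal(chip_overlap_fraction(iv(0L, 10L), iv(10L, 20L)), 0)
})

test_that("hybrid zones implement the rescue rule and partition", {
  tss <- iv(100000L, 100001L)
  k4 <- iv(109000L, 111000L)
  lab <- hybrid_zone_label(
    rbind(iv(100300L, 100320L),   # 300 bp away -> positive zone
          iv(90000L, 90050L),     # 10 kb away, no H3K4me3 -> negative
          iv(110000L, 110050L),   # 10 kb away but H3K4me3 -> rescued
          iv(165000L, 165050L)),  # 65 kb away -> outside
    tss, k4)
  expect_equal(lab, c("positive_zone", "negative_zone", "positive_zone",
                      "outside"))
  # zone labels are exhaustive and mutually exclusive
  set.seed(12)
  preds <- iv(sample.int(3e5, 300), numeric(300))
  preds$end <- preds$start + 25L
  lab2 <- hybrid_zone_label(preds, tss, k4)
  expect_true(all(lab2 %in% c("positive_zone", "negative_zone", "outside")))
  # widening the positive zone never turns a positive into a negative
  lab3 <- hybrid_zone_label(preds, tss, k4, pos_half_width = 1000L)
  expect_true(all(lab3[lab2 == "positive_zone"] == "positive_zone"))
})

test_that("ROC points, AUC and monotonicity", {
  scores <- c(0.9, 0.8, 0.4, 0.2)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_points(scores, pos)
  expect_equal(roc$auc, 1.0)
  one <- roc_points(scores, pos, thresholds = 0.5)
  expect_equal(one$points$fpr, 0)
  expect_equal(one$points$tpr, 1)
  # TPR/FPR are non-decreasing as the threshold decreases; AUC in [0,1]
  set.seed(9)
  s <- runif(500); y <- runif(500) < 0.4
  r <- roc_points(s, y)
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  # agrees with an independent implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(r$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                levels = c(FALSE, TRUE),
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
  expect_error(roc_points(s, rep(TRUE, 500)), "both")
})

test_that("gene-level counts give positive-zone precedence", {
  genes <- iv(c(100000L, 300000L, 500000L), c(100001L, 300001L, 500001L),
              name = c("g1", "g2", "g3"))
  preds <- rbind(iv(100100L, 100150L),  # g1 positive zone
                 iv(110000L, 110050L),  # g1 negative zone
                 iv(310000L, 310050L))  # g2 negative zone only
  counts <- gene_level_counts(preds, genes)
  expect_equal(unname(counts), c(1L, 1L))  # g1 TP (not FP), g2 FP, g3 none
})

test_that("genomic location priority is promoter > junction > exon > intron", {
  promoters <- iv(1000L, 2501L)
  junctions <- iv(c(5950L, 7950L), c(6051L, 8051L))
  exons <- iv(2500L, 6000L)
  introns <- iv(6000L, 8000L)
  # 1 bp into the promoter, 200 bp in the exon -> promoter wins
  expect_equal(assign_genomic_location(iv(2500L, 2700L), promoters,
                                       junctions, exons, introns),
               "promoter")
  # overlapping exon and a junction window -> junction wins
  expect_equal(assign_genomic_location(iv(5960L, 5990L), promoters,
                                       junctions, exons, introns),
               "junction")
  expect_equal(assign_genomic_location(iv(3000L, 3100L), promoters,
                                       junctions, exons, introns), "exon")
  expect_equal(assign_genomic_location(iv(7000L, 7100L), promoters,
                                       junctions, exons, introns), "intron")
  expect_true(is.na(assign_genomic_location(iv(50000L, 50100L), promoters,
                                            junctions, exons, introns)))
  # row order of the tracks is irrelevant
  expect_equal(
    assign_genomic_location(iv(5960L, 5990L), promoters,
                            junctions[2:1, ], exons, introns),
    "junction")
})

test_that("promoter windows are strand-aware", {
  genes <- data.frame(chrom = "c1", start = c(10000L, 50000L),
                      end = c(10001L, 50001L), strand = c("+", "-"))
  pw <- promoter_windows(genes)
  expect_equal(pw$start, c(9000L, 49500L))
  expect_equal(pw$end, c(10501L, 51001L))
})

test_that("reference peaks are matched by any-overlap", {
  ref <- iv(c(0L, 100L, 200L), c(50L, 150L, 250L))
  preds <- rbind(iv(10L, 20L), iv(15L, 30L))
  m <- match_to_reference_peaks(ref, preds)
  expect_equal(m, c(TRUE, FALSE, FALSE))  # two hits count once
  expect_equal(match_to_reference_peaks(ref, preds[0, ]),
               rep(FALSE, 3))
})
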