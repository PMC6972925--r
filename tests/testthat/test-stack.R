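# Classifier stack machinery on constructed data plus a small end-to-end fit.

test_that("per-feature SVMs separate well-separated Gaussians", {
  set.seed(1)
  n <- 60; d <- 10
  X <- rbind(matrix(rnorm(n * d, -2, 0.3), n, d),
             matrix(rnorm(n * d, 2, 0.3), n, d))
  y <- rep(c("negative", "positive"), each = n)
  svms <- train_feature_svms(list(f1 = X), y,
                             cost_grid = 2^c(0, 4),
                             gamma_grid = 2^c(-6, -2),
                             cv_folds = 5L, seed = 3L)
  expect_gte(attr(svms$f1, "cv_accuracy"), 0.99)
  # probabilistic outputs: in [0,1], class columns sum to 1
  p <- predict(svms$f1, X, probability = TRUE)
  probs <- attr(p, "probabilities")
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, 2 * n))
  # same seed -> identical hyperparameter choice
  svms2 <- train_feature_svms(list(f1 = X), y, cost_grid = 2^c(0, 4),
                              gamma_grid = 2^c(-6, -2), cv_folds = 5L,
                              seed = 3L)
  expect_identical(attr(svms$f1, "cost"), attr(svms2$f1, "cost"))
  expect_identical(attr(svms$f1, "gamma"), attr(svms2$f1, "gamma"))
  expect_error(train_feature_svms(list(f1 = X), rep("positive", 2 * n)),
               "single class")
})

test_that("the structural combiner learns from one informative column", {
  set.seed(2)
  n <- 120
  y <- rep(c("negative", "positive"), each = n / 2)
  P <- matrix(runif(n * 13), n, 13,
              dimnames = list(NULL, paste0("f", sprintf("%02d", 1:13))))
  P[, "f07"] <- ifelse(y == "positive", 0.95, 0.05) + rnorm(n, 0, 0.02)
  idx <- sample(n, 80)
  comb <- train_structural_combiner(P[idx, ], y[idx], tune_iters = 8L,
                                    cv_folds = 5L, cv_repeats = 2L,
                                    seed = 4L)
  held <- setdiff(seq_len(n), idx)
  scores <- cagetss:::.sgb_score(comb, P[held, ])
  expect_true(all(scores >= 0 & scores <= 1))
  acc <- mean((scores >= 0.5) == (y[held] == "positive"))
  expect_gte(acc, 0.95)
  # name-keyed features: permuting columns leaves predictions unchanged
  perm <- sample(13)
  expect_equal(cagetss:::.sgb_score(comb, P[held, perm]), scores)
})

test_that("the motif booster handles degenerate constant features", {
  set.seed(5)
  n <- 80
  y <- rep(c("negative", "positive"), each = n / 2)
  M <- matrix(1, n, 13, dimnames = list(NULL, paste0("m", 1:13)))
  fit <- train_motif_model(M, y, tune_iters = 4L, cv_folds = 4L,
                           cv_repeats = 2L, seed = 6L)
  pred <- cagetss:::.sgb_score(fit, M)
  expect_equal(length(unique(round(pred, 10))), 1L)
  # reproducible under a fixed seed
  fit2 <- train_motif_model(M, y, tune_iters = 4L, cv_folds = 4L,
                            cv_repeats = 2L, seed = 6L)
  expect_identical(fit$params, fit2$params)
})

test_that("the final booster integrates three informative inputs", {
  set.seed(7)
  n <- 140
  y <- rep(c("negative", "positive"), each = n / 2)
  F <- cbind(structural_score = ifelse(y == "positive", 0.9, 0.1),
             motif_score = ifelse(y == "positive", 0.85, 0.15),
             log10_tpm = ifelse(y == "positive", 1.5, 0.2))
  F <- F + rnorm(length(F), 0, 0.02)
  idx <- sample(n, 100)
  fit <- train_final_model(F[idx, ], y[idx], tune_iters = 6L,
                           cv_folds = 5L, cv_repeats = 2L, seed = 8L)
  held <- setdiff(seq_len(n), idx)
  acc <- mean((cagetss:::.sgb_score(fit, F[held, ]) >= 0.5) ==
              (y[held] == "positive"))
  expect_gte(acc, 0.99)
})

test_that("a small end-to-end fit produces calibrated, ordered scores", {
  stack <- get_tiny_stack()
  bench <- get_tiny_bench()
  clusters <- get_tiny_clusters()
  expect_s3_class(stack, "tss_stack")
  pred <- predict(stack, clusters, bench$genome)
  expect_equal(nrow(pred), nrow(clusters))
  for (col in c("structural_score", "motif_score", "final_score"))
    expect_true(all(pred[[col]] >= 0 & pred[[col]] <= 1))
  # training positives outscore training negatives on average
  truth <- truth_labels(clusters, bench$promoters)
  expect_gt(mean(pred$final_score[truth]), mean(pred$final_score[!truth]))
  # strict calls nest inside loose calls
  strict <- classify_predictions(pred, 0.9)
  loose <- classify_predictions(pred, 0.5)
  expect_true(all(!strict | loose))
  # scoring is invariant to cluster order
  ord <- sample(nrow(clusters))
  pred2 <- predict(stack, clusters[ord, ], bench$genome)
  expect_equal(pred2$final_score, pred$final_score[ord])
  # config mismatch is caught before scoring
  expect_error(predict(stack, clusters, bench$genome,
                       config = tss_config(struct_half_width = 99L)),
               "snapshot")
  # print and summary run quietly
  expect_output(print(stack), "stack")
  expect_output(summary(stack), "AUROC")
})

test_that("save/load round-trips to bit-identical predictions", {
  stack <- get_tiny_stack()
  bench <- get_tiny_bench()
  clusters <- get_tiny_clusters()
  before <- predict(stack, clusters, bench$genome)
  dir <- file.path(tempdir(), "stackdir")
  save_stack(stack, dir)
  re <- load_stack(dir)
  after <- predict(re, clusters, bench$genome)
  expect_identical(before$final_score, after$final_score)
  expect_identical(before$structural_score, after$structural_score)
  # tampering with the manifest motif list is detected
  mf <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  manifest$motif_ids <- manifest$motif_ids[-1]
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  expect_error(load_stack(dir), "motif list")
  expect_error(load_stack(file.path(tempdir(), "no_such_stack")),
               "no saved stack")
  unlink(dir, recursive = TRUE)
})
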