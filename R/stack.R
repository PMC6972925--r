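# The layered classifier: 13 per-feature probabilistic SVMs, a structural
# combiner (stochastic gradient boosting), a motif booster, and a final
# booster over (structural score, motif score, log10 tpm).

# ---- internals -------------------------------------------------------------

.auc_mw <- function(scores, positive) {
  # Mann-Whitney AUC; positive is logical
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold ids, deterministic under the current RNG state
.make_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

.svm_fit <- function(X, y, cost, gamma, probability = FALSE) {
  suppressWarnings(e1071::svm(X, y, kernel = "radial", cost = cost,
                              gamma = gamma, probability = probability,
                              scale = TRUE))
}

.svm_prob <- function(model, X) {
  p <- predict(model, X, probability = TRUE)
  attr(p, "probabilities")[, "positive"]
}

# ---- tier 1: per-feature SVMs ---------------------------------------------

#' Train the 13 per-feature probabilistic SVMs
#'
#' One RBF SVM per structural feature, with (C, gamma) chosen by grid search
#' maximizing accuracy under stratified k-fold cross-validation, then refit
#' on the full tier-1 subset with Platt-style probability calibration.
#' Deterministic hyperparameter choice given `seed`.
#'
#' @param feature_matrices Named list of numeric matrices (rows = clusters),
#'   one per structural feature.
#' @param labels Factor with levels `negative`, `positive`.
#' @param cost_grid,gamma_grid Log-spaced search grids.
#' @param cv_folds Folds, default 10.
#' @param seed RNG seed for fold assignment.
#' @return Named list of fitted SVMs; each carries `cv_accuracy`, `cost`,
#'   `gamma` attributes.
#' @export
train_feature_svms <- function(feature_matrices, labels,
                               cost_grid = 2^c(-5, 2, 8, 15),
                               gamma_grid = 2^c(-15, -9, -3, 3),
                               cv_folds = 10L, seed = 1L) {
  y <- .as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("tier-1 subset contains a single class", call. = FALSE)
  set.seed(seed)
  folds <- .make_folds(y, cv_folds)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  out <- lapply(names(feature_matrices), function(feat) {
    X <- feature_matrices[[feat]]
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        m <- .svm_fit(X[tr, , drop = FALSE], y[tr],
                      grid$cost[g], grid$gamma[g])
        correct <- correct + sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
    best <- which.max(acc)  # first maximum: deterministic tie-break
    fit <- .svm_fit(X, y, grid$cost[best], grid$gamma[best],
                    probability = TRUE)
    attr(fit, "cv_accuracy") <- acc[best]
    attr(fit, "cost") <- grid$cost[best]
    attr(fit, "gamma") <- grid$gamma[best]
    fit
  })
  names(out) <- names(feature_matrices)
  out
}

.as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (all(labels %in% c("positive", "negative")))
    return(factor(labels, levels = c("negative", "positive")))
  stop("labels must be 'positive'/'negative'", call. = FALSE)
}

# 13 SVM probability columns, name-keyed and column-sorted
.svm_prob_matrix <- function(svms, feature_matrices) {
  feats <- sort(names(svms))
  out <- vapply(feats, function(f) .svm_prob(svms[[f]],
                                             feature_matrices[[f]]),
                numeric(nrow(feature_matrices[[feats[1]]])))
  out <- matrix(out, ncol = length(feats),
                dimnames = list(NULL, feats))
  out
}

# ---- stochastic gradient boosting tiers -----------------------------------

# random-search + CV tuning of one boosting model.  Each of `tune_iters`
# candidates is scored with one k-fold CV (AUC); the winner's performance is
# then re-estimated with `cv_repeats` repeats of k-fold CV and the model is
# refit on all rows.
.train_sgb <- function(X, y, tune_iters = 50L, cv_folds = 10L,
                       cv_repeats = 10L, seed = 1L) {
  stopifnot(is.matrix(X))
  y <- .as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("boosting subset contains a single class", call. = FALSE)
  X <- X[, order(colnames(X)), drop = FALSE]  # name-keyed column order
  ybin <- as.integer(y == "positive")
  set.seed(seed)
  cand <- data.frame(
    nrounds = sample(50:500, tune_iters, replace = TRUE),
    max_depth = sample(1:5, tune_iters, replace = TRUE),
    eta = exp(runif(tune_iters, log(0.01), log(0.3))),
    xseed = sample.int(1e6, tune_iters, replace = TRUE)
  )
  folds <- .make_folds(y, cv_folds)
  cv_auc_one <- function(par, folds) {
    preds <- numeric(length(ybin))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      b <- .xgb_fit(X[tr, , drop = FALSE], ybin[tr], par)
      preds[!tr] <- .xgb_predict(b, X[!tr, , drop = FALSE])
    }
    .auc_mw(preds, ybin == 1L)
  }
  aucs <- vapply(seq_len(tune_iters),
                 function(i) cv_auc_one(cand[i, ], folds), numeric(1))
  best <- cand[which.max(aucs), ]
  rep_auc <- vapply(seq_len(cv_repeats), function(r)
    cv_auc_one(best, .make_folds(y, cv_folds)), numeric(1))
  fit <- .xgb_fit(X, ybin, best)
  list(booster = fit, params = best, cv_auc = mean(rep_auc),
       cv_auc_sd = stats::sd(rep_auc), feature_names = colnames(X))
}

.xgb_fit <- function(X, ybin, par) {
  dtrain <- xgboost::xgb.DMatrix(X, label = ybin)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = par$max_depth,
                  eta = par$eta, subsample = 0.5, nthread = 1,
                  seed = par$xseed),
    data = dtrain, nrounds = par$nrounds, verbose = 0)
}

.xgb_predict <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(X))
}

#' Train the structural combiner
#'
#' Stochastic gradient boosting over the 13 per-feature SVM probabilities,
#' evaluated on the tier-2 subset (disjoint from the SVM training subset).
#' Tuned by random search (`tune_iters` candidates) under k-fold CV; the
#' chosen candidate's performance is estimated with repeated CV.
#'
#' @param svm_probs Matrix of SVM probabilities (columns named by feature).
#' @param labels `positive`/`negative` labels for the tier-2 rows.
#' @param tune_iters,cv_folds,cv_repeats Tuning regime (defaults 50/10/10).
#' @param seed RNG seed.
#' @return Fitted boosting model (list; see details in [fit_tss_stack()]).
#' @export
train_structural_combiner <- function(svm_probs, labels, tune_iters = 50L,
                                      cv_folds = 10L, cv_repeats = 10L,
                                      seed = 1L) {
  .train_sgb(svm_probs, labels, tune_iters, cv_folds, cv_repeats, seed)
}

#' Train the motif booster
#'
#' Stochastic gradient boosting over the 13 TRAP motif affinities, trained
#' on the tier-1 subset.
#'
#' @param motif_matrix Affinity matrix (columns named by motif).
#' @inheritParams train_structural_combiner
#' @return Fitted boosting model.
#' @export
train_motif_model <- function(motif_matrix, labels, tune_iters = 50L,
                              cv_folds = 10L, cv_repeats = 10L, seed = 1L) {
  .train_sgb(motif_matrix, labels, tune_iters, cv_folds, cv_repeats, seed)
}

#' Train the final booster
#'
#' Stochastic gradient boosting over (structural score, motif score,
#' log10(tpm + eps)), trained on the tier-3 subset.
#'
#' @param features Matrix with columns `structural_score`, `motif_score`,
#'   `log10_tpm`.
#' @inheritParams train_structural_combiner
#' @return Fitted boosting model.
#' @export
train_final_model <- function(features, labels, tune_iters = 50L,
                              cv_folds = 10L, cv_repeats = 10L, seed = 1L) {
  .train_sgb(features, labels, tune_iters, cv_folds, cv_repeats, seed)
}

.sgb_score <- function(model, X) {
  X <- X[, model$feature_names, drop = FALSE]
  .xgb_predict(model$booster, X)
}

# ---- featurization shared by fit and predict ------------------------------

.featurize <- function(clusters, genome, resources, config) {
  feats <- lapply(resources$tables, function(tab)
    .structural_matrix(genome, clusters, tab, config$struct_half_width,
                       config$smooth_w))
  motif <- .motif_matrix(genome, clusters, resources$motif_models,
                         config$motif_half_width)
  colnames(motif) <- names(resources$motif_models)
  list(structural = feats, motif = motif,
       log10_tpm = log10(clusters$tpm + config$log_tpm_eps))
}

# ---- the fitting front-end ------------------------------------------------

#' Fit the full TSS classifier stack
#'
#' Splits the labeled clusters into four disjoint stratified subsets
#' (default 50/20/15/15), trains the 13 per-feature SVMs and the motif
#' booster on subset 1, the structural combiner on subset 2, the final
#' booster on subset 3, and evaluates on the held-out test subset (never
#' used in tuning).  All randomness funnels through `seed`.
#'
#' @param labeled Labeled cluster table from [label_clusters()] (needs
#'   `tpm` and `label` columns).
#' @param genome `DNAStringSet` reference.
#' @param config [tss_config()] snapshot used for all featurization.
#' @param seed Integer run-level seed.
#' @return An object of class `tss_stack` with components `feature_svms`,
#'   `structural_combiner`, `motif_model`, `final_model`, `config`, `seed`,
#'   `test_scores` (held-out predictions) and `metrics`.
#' @export
fit_tss_stack <- function(labeled, genome, config = tss_config(),
                          seed = 1L) {
  stopifnot(inherits(config, "tss_config"))
  subsets <- split_four_way(labeled, config$split_fractions, seed = seed)
  check_tier_isolation(subsets)
  resources <- .load_resources(config)

  f1 <- .featurize(subsets$subset1, genome, resources, config)
  f2 <- .featurize(subsets$subset2, genome, resources, config)
  f3 <- .featurize(subsets$subset3, genome, resources, config)
  ft <- .featurize(subsets$test, genome, resources, config)

  svms <- train_feature_svms(f1$structural, subsets$subset1$label,
                             cost_grid = config$svm_cost_grid,
                             gamma_grid = config$svm_gamma_grid,
                             cv_folds = config$cv_folds, seed = seed)
  motif_model <- train_motif_model(f1$motif, subsets$subset1$label,
                                   tune_iters = config$sgb_tune_iters,
                                   cv_folds = config$cv_folds,
                                   cv_repeats = config$sgb_cv_repeats,
                                   seed = seed + 1L)
  p2 <- .svm_prob_matrix(svms, f2$structural)
  combiner <- train_structural_combiner(p2, subsets$subset2$label,
                                        tune_iters = config$sgb_tune_iters,
                                        cv_folds = config$cv_folds,
                                        cv_repeats = config$sgb_cv_repeats,
                                        seed = seed + 2L)
  p3 <- .svm_prob_matrix(svms, f3$structural)
  final_feats <- cbind(structural_score = .sgb_score(combiner, p3),
                       motif_score = .sgb_score(motif_model, f3$motif),
                       log10_tpm = f3$log10_tpm)
  final_model <- train_final_model(final_feats, subsets$subset3$label,
                                   tune_iters = config$sgb_tune_iters,
                                   cv_folds = config$cv_folds,
                                   cv_repeats = config$sgb_cv_repeats,
                                   seed = seed + 3L)

  stack <- structure(
    list(feature_svms = svms, structural_combiner = combiner,
         motif_model = motif_model, final_model = final_model,
         config = config, seed = seed,
         motif_ids = names(resources$motif_models),
         feature_names = names(resources$tables),
         version = as.character(utils::packageVersion("cagetss"))),
    class = "tss_stack")

  test_pred <- .score_featurized(stack, ft, subsets$test)
  test_pred$label <- subsets$test$label
  auc <- .auc_mw(test_pred$final_score, test_pred$label == "positive")
  stack$test_scores <- test_pred
  stack$metrics <- list(
    test_auroc = auc,
    test_n = nrow(test_pred),
    svm_cv_accuracy = vapply(svms, attr, numeric(1), "cv_accuracy"),
    motif_cv_auc = motif_model$cv_auc,
    structural_cv_auc = combiner$cv_auc,
    final_cv_auc = final_model$cv_auc)
  stack
}

.score_featurized <- function(stack, feats, clusters) {
  p <- .svm_prob_matrix(stack$feature_svms, feats$structural)
  structural <- .sgb_score(stack$structural_combiner, p)
  motif <- .sgb_score(stack$motif_model, feats$motif)
  final <- .sgb_score(stack$final_model,
                      cbind(structural_score = structural,
                            motif_score = motif,
                            log10_tpm = feats$log10_tpm))
  out <- clusters[, intersect(c("chrom", "start", "end", "strand",
                                "representative", "raw_count", "tpm"),
                              names(clusters)), drop = FALSE]
  out$structural_score <- structural
  out$motif_score <- motif
  out$final_score <- final
  rownames(out) <- NULL
  out
}

#' Score tag clusters with a fitted stack
#'
#' @param object A fitted `tss_stack`.
#' @param clusters Cluster table with `tpm` (see [call_peaks()]).
#' @param genome `DNAStringSet` reference.
#' @param config Optional config; must equal the stack's snapshot (a
#'   mismatch is an error, caught before any scoring).
#' @param ... Unused.
#' @return Prediction table: the cluster columns plus `structural_score`,
#'   `motif_score`, `final_score`, all in \[0, 1\], one row per input
#'   cluster in input order.
#' @export
predict.tss_stack <- function(object, clusters, genome, config = NULL, ...) {
  if (!is.null(config) && !identical(unclass(config)[.feat_keys()],
                                     unclass(object$config)[.feat_keys()]))
    stop("featurizer config does not match the fitted stack's snapshot",
         call. = FALSE)
  if (is.null(clusters$tpm))
    stop("clusters need a tpm column; run normalize_tpm()", call. = FALSE)
  resources <- .load_resources(object$config)
  if (!identical(names(resources$motif_models), object$motif_ids))
    stop("motif set does not match the fitted stack", call. = FALSE)
  feats <- .featurize(clusters, genome, resources, object$config)
  .score_featurized(object, feats, clusters)
}

.feat_keys <- function() c("struct_half_width", "smooth_w",
                           "motif_half_width", "trap_lambda",
                           "trap_pseudocount", "structural_dir",
                           "motif_file", "log_tpm_eps")

#' Binary calls at a score cutoff
#'
#' Applied only at reporting time; 0.5 is the loose cutoff, 0.9 the strict
#' one.
#'
#' @param predictions Prediction table from [predict.tss_stack()].
#' @param cutoff Score threshold in \[0, 1\].
#' @return Logical vector: `final_score >= cutoff`.
#' @export
classify_predictions <- function(predictions, cutoff = 0.5) {
  predictions$final_score >= cutoff
}

#' @export
print.tss_stack <- function(x, ...) {
  cat("TSS classifier stack (cagetss)\n")
  cat(sprintf("  %d per-feature SVMs + structural/motif/final boosters\n",
              length(x$feature_svms)))
  cat(sprintf("  trained with seed %d; held-out AUROC %.3f (n = %d)\n",
              x$seed, x$metrics$test_auroc, x$metrics$test_n))
  invisible(x)
}

#' @export
summary.tss_stack <- function(object, ...) {
  m <- object$metrics
  cat("TSS classifier stack\n")
  cat(sprintf("held-out test AUROC : %.3f (n = %d)\n", m$test_auroc,
              m$test_n))
  cat(sprintf("structural combiner CV AUC : %.3f\n", m$structural_cv_auc))
  cat(sprintf("motif booster CV AUC       : %.3f\n", m$motif_cv_auc))
  cat(sprintf("final booster CV AUC       : %.3f\n", m$final_cv_auc))
  cat("per-feature SVM CV accuracy:\n")
  acc <- sort(m$svm_cv_accuracy, decreasing = TRUE)
  for (f in names(acc)) cat(sprintf("  %-24s %.3f\n", f, acc[f]))
  imp <- xgboost::xgb.importance(model = object$final_model$booster)
  cat("final booster feature importance (gain):\n")
  for (i in seq_len(nrow(imp)))
    cat(sprintf("  %-18s %.3f\n", imp$Feature[i], imp$Gain[i]))
  invisible(m)
}

#' @export
plot.tss_stack <- function(x, ...) {
  sc <- x$test_scores
  roc <- roc_points(sc$final_score, sc$label == "positive")
  plot(roc$points$fpr, roc$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Held-out ROC (AUC = %.3f)", roc$auc), ...)
  abline(0, 1, lty = 3)
  invisible(roc)
}

# ---- persistence ----------------------------------------------------------

#' Save a fitted stack to a directory
#'
#' Writes a JSON manifest (config snapshot, seed, motif list, feature list,
#' package version) plus the serialized sub-models.  [load_stack()] restores
#' a stack producing bit-identical predictions.
#'
#' @param stack Fitted `tss_stack`.
#' @param path Output directory (created).
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = stack$version, seed = stack$seed,
                   motif_ids = stack$motif_ids,
                   feature_names = stack$feature_names,
                   config = unclass(stack$config))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  payload <- stack
  for (tier in c("structural_combiner", "motif_model", "final_model"))
    payload[[tier]]$booster <- xgboost::xgb.save.raw(payload[[tier]]$booster)
  saveRDS(payload, file.path(path, "stack.rds"))
  invisible(path)
}

#' Load a fitted stack saved by [save_stack()]
#'
#' @param path Stack directory.
#' @return A `tss_stack`.
#' @export
load_stack <- function(path) {
  mf <- file.path(path, "manifest.json"); rds <- file.path(path, "stack.rds")
  if (!file.exists(mf) || !file.exists(rds))
    stop("no saved stack at ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  stack <- readRDS(rds)
  for (tier in c("structural_combiner", "motif_model", "final_model"))
    stack[[tier]]$booster <- xgboost::xgb.load.raw(stack[[tier]]$booster)
  if (!identical(as.character(manifest$motif_ids), stack$motif_ids))
    stop("stack manifest motif list does not match the serialized models",
         call. = FALSE)
  if (!identical(as.character(manifest$feature_names), stack$feature_names))
    stop("stack manifest feature list does not match the serialized models",
         call. = FALSE)
  stack
}
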