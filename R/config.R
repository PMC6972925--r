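# Pipeline configuration: one object carries every tunable so that a fitted
# stack can snapshot the exact featurization it was trained with.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the peak caller, the featurizers and
#' the model stack.  Defaults follow the standard pipeline settings: mapq
#' 10, clustering gap 50 bp, 0.5 tpm cutoff, 1001-nt structural windows
#' smoothed with an 11-nt moving average, 100-bp motif windows, TRAP
#' lambda 0.7 with `ln R0 = 0.584 W - 5.66`, an RBF SVM tuned on a coarse
#' log-spaced (C, gamma) grid under 10-fold CV, and stochastic gradient
#' boosting tuned by 50-iteration random search.
#'
#' @param min_mapq Mapping-quality threshold (inclusive).
#' @param max_gap CTSS clustering gap in bp.
#' @param tpm_cutoff Expression filter in tags per million.
#' @param struct_half_width Structural window half-width in nt.
#' @param smooth_w Odd smoothing window for structural profiles.
#' @param motif_half_width Motif window half-width in nt (50 = 100-bp
#'   window).
#' @param trap_lambda,trap_pseudocount TRAP energy-model parameters.
#' @param svm_cost_grid,svm_gamma_grid RBF SVM search grids.
#' @param cv_folds Cross-validation folds for all tuning.
#' @param sgb_tune_iters Random-search iterations per boosting tier.
#' @param sgb_cv_repeats Repeats of k-fold CV when estimating the chosen
#'   boosting configuration's performance.
#' @param split_fractions Four-way training split fractions.
#' @param structural_dir Directory of structural tables (NULL = packaged).
#' @param motif_file JASPAR motif file (NULL = packaged).
#' @param log_tpm_eps Epsilon inside `log10(tpm + eps)`.
#' @return An object of class `tss_config` (a validated list).
#' @export
tss_config <- function(min_mapq = 10L, max_gap = 50L, tpm_cutoff = 0.5,
                       struct_half_width = 500L, smooth_w = 11L,
                       motif_half_width = 50L, trap_lambda = 0.7,
                       trap_pseudocount = 1,
                       svm_cost_grid = 2^c(-5, 2, 8, 15),
                       svm_gamma_grid = 2^c(-15, -9, -3, 3),
                       cv_folds = 10L, sgb_tune_iters = 50L,
                       sgb_cv_repeats = 10L,
                       split_fractions = c(0.50, 0.20, 0.15, 0.15),
                       structural_dir = NULL, motif_file = NULL,
                       log_tpm_eps = 1e-6) {
  cfg <- list(min_mapq = min_mapq, max_gap = max_gap,
              tpm_cutoff = tpm_cutoff,
              struct_half_width = as.integer(struct_half_width),
              smooth_w = as.integer(smooth_w),
              motif_half_width = as.integer(motif_half_width),
              trap_lambda = trap_lambda,
              trap_pseudocount = trap_pseudocount,
              svm_cost_grid = svm_cost_grid,
              svm_gamma_grid = svm_gamma_grid,
              cv_folds = as.integer(cv_folds),
              sgb_tune_iters = as.integer(sgb_tune_iters),
              sgb_cv_repeats = as.integer(sgb_cv_repeats),
              split_fractions = split_fractions,
              structural_dir = structural_dir, motif_file = motif_file,
              log_tpm_eps = log_tpm_eps)
  if (cfg$smooth_w %% 2 == 0) stop("smooth_w must be odd", call. = FALSE)
  if (cfg$trap_lambda <= 0) stop("trap_lambda must be > 0", call. = FALSE)
  class(cfg) <- "tss_config"
  cfg
}

#' @export
print.tss_config <- function(x, ...) {
  cat("cagetss pipeline configuration\n")
  cat(sprintf("  peak calling : mapq >= %d, gap < %d bp, tpm >= %.2f\n",
              x$min_mapq, x$max_gap, x$tpm_cutoff))
  cat(sprintf("  structural   : window %d nt, smoothing %d nt\n",
              2L * x$struct_half_width + 1L, x$smooth_w))
  cat(sprintf("  motifs       : window %d nt, TRAP lambda %.2f\n",
              2L * x$motif_half_width + 1L, x$trap_lambda))
  cat(sprintf("  tuning       : %d-fold CV; SVM grid %d x %d; SGB %d draws\n",
              x$cv_folds, length(x$svm_cost_grid), length(x$svm_gamma_grid),
              x$sgb_tune_iters))
  invisible(x)
}

# load the feature resources named by a config
.load_resources <- function(config) {
  tables <- if (is.null(config$structural_dir)) default_structural_tables()
            else default_structural_tables(config$structural_dir)
  pfms <- if (is.null(config$motif_file)) default_motif_pfms()
          else read_jaspar_pfm(config$motif_file)
  models <- .build_models(pfms, lambda = config$trap_lambda,
                          pseudocount = config$trap_pseudocount)
  list(tables = tables, motif_models = models)
}
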