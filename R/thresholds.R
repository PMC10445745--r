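#' Analysis thresholds
#'
#' Container for every fixed threshold used across the pipeline. Defaults are
#' the values used throughout the analysis; any subset can be overridden,
#' either directly or via a YAML config file (see [read_config()]).
#'
#' @param de_fdr FDR gate for differential expression calls.
#' @param de_lfc absolute log2-fold-change gate for differential expression.
#' @param hk_lfc maximum absolute log2-fold-change between successive days for
#'   a housekeeping (stably expressed) gene.
#' @param hk_min_expr minimum mean normalized expression for a housekeeping
#'   gene.
#' @param tf_expr_min minimum replicate-mean normalized expression (at any
#'   timepoint) for a TF to count as expressed.
#' @param atac_dynamic_lfc log2-fold-change gate defining dynamic
#'   (opening/closing) accessibility peaks.
#' @param model_dynamic_lfc looser log2-fold-change gate defining the dynamic
#'   peak set used by the logistic motif-importance model.
#' @param motif_pvalue p-value threshold for PWM scan occurrences.
#' @param subnucleosomal_max_fragment maximum ATAC fragment size (bp) assumed
#'   for the input tracks (informational; filtering happens upstream).
#' @param fp_central_halfwidth half-width (bp) of the central footprint region
#'   around a motif centre.
#' @param fp_flank_width width (bp) of each flanking region.
#' @param fp_aggregate_halfwidth half-width (bp) of aggregate footprint
#'   windows around motif occurrences.
#' @param corr_call_threshold absolute median correlation required to call a
#'   TF activator- or repressor-like.
#' @param corr_call_p p-value gate for regulator calls (Wilcoxon rank-sum
#'   against the background distribution).
#' @param gmm_n_init number of random initializations per GMM fit.
#' @param logit_n_seeds number of seeded refits of the logistic model.
#' @param logit_cv_folds number of cross-validation folds for choosing the
#'   regularization strength.
#' @param promoter_window bp either side of a TSS counted as promoter.
#' @param pattern_delta z-score margin used when assigning trajectory
#'   patterns to clusters.
#'
#' @return An object of class `ef_thresholds` (a validated named list).
#' @export
ef_thresholds <- function(de_fdr = 0.001,
                          de_lfc = 1.5,
                          hk_lfc = 0.1,
                          hk_min_expr = 30,
                          tf_expr_min = 50,
                          atac_dynamic_lfc = 1.5,
                          model_dynamic_lfc = 1.0,
                          motif_pvalue = 1e-4,
                          subnucleosomal_max_fragment = 100L,
                          fp_central_halfwidth = 12L,
                          fp_flank_width = 60L,
                          fp_aggregate_halfwidth = 100L,
                          corr_call_threshold = 0.5,
                          corr_call_p = 1e-10,
                          gmm_n_init = 20L,
                          logit_n_seeds = 10L,
                          logit_cv_folds = 5L,
                          promoter_window = 1000L,
                          pattern_delta = 0.5) {
  th <- list(
    de_fdr = de_fdr, de_lfc = de_lfc, hk_lfc = hk_lfc,
    hk_min_expr = hk_min_expr, tf_expr_min = tf_expr_min,
    atac_dynamic_lfc = atac_dynamic_lfc,
    model_dynamic_lfc = model_dynamic_lfc,
    motif_pvalue = motif_pvalue,
    subnucleosomal_max_fragment = as.integer(subnucleosomal_max_fragment),
    fp_central_halfwidth = as.integer(fp_central_halfwidth),
    fp_flank_width = as.integer(fp_flank_width),
    fp_aggregate_halfwidth = as.integer(fp_aggregate_halfwidth),
    corr_call_threshold = corr_call_threshold,
    corr_call_p = corr_call_p,
    gmm_n_init = as.integer(gmm_n_init),
    logit_n_seeds = as.integer(logit_n_seeds),
    logit_cv_folds = as.integer(logit_cv_folds),
    promoter_window = as.integer(promoter_window),
    pattern_delta = pattern_delta
  )
  validate_thresholds(th)
  structure(th, class = "ef_thresholds")
}

validate_thresholds <- function(th) {
  probs <- c("de_fdr", "motif_pvalue", "corr_call_p")
  for (p in probs) {
    if (!is.numeric(th[[p]]) || th[[p]] <= 0 || th[[p]] >= 1) {
      stop(sprintf("threshold '%s' must be a probability in (0,1)", p))
    }
  }
  widths <- c("subnucleosomal_max_fragment", "fp_central_halfwidth",
              "fp_flank_width", "fp_aggregate_halfwidth", "promoter_window")
  for (w in widths) {
    if (th[[w]] < 1L) stop(sprintf("threshold '%s' must be a positive integer", w))
  }
  counts <- c("gmm_n_init", "logit_n_seeds", "logit_cv_folds")
  for (k in counts) {
    if (th[[k]] < 1L) stop(sprintf("threshold '%s' must be >= 1", k))
  }
  if (th$de_lfc < th$model_dynamic_lfc) {
    stop("de_lfc must be >= model_dynamic_lfc")
  }
  invisible(th)
}

#' @export
print.ef_thresholds <- function(x, ...) {
  cat("eyefield thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read thresholds from a YAML config file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path path to a YAML file whose top-level keys are threshold names.
#' @return An `ef_thresholds` object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(ef_thresholds))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(ef_thresholds, cfg)
}
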