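#' Match expression and accessibility trajectories over shared days
#'
#' Builds the day grid shared by RNA-seq and ATAC-seq (days 0,1,2,3,5 by
#' default; day 4 accessibility is absent from the design), using
#' replicate-mean expression and the GFP-positive branch at days >= 4.
#'
#' @param norm_expr normalized expression matrix.
#' @param meta sample metadata.
#' @param days shared day grid (default `c(0,1,2,3,5)`).
#' @return Matrix genes x days (`d0`, `d1`, ...) of replicate-mean
#'   expression on the shared grid.
#' @export
matched_trajectories <- function(norm_expr, meta, days = c(0, 1, 2, 3, 5)) {
  if (length(days) < 4) stop("need >= 4 shared timepoints")
  dm <- day_mean_matrix(norm_expr, meta, days = days)
  want <- paste0("d", days)
  if (!all(want %in% colnames(dm))) {
    stop("expression is missing samples for day(s): ",
         paste(setdiff(want, colnames(dm)), collapse = ", "),
         " (GFP+ branch required at days >= 4)")
  }
  dm[, want, drop = FALSE]
}

#' Correlate TF expression with accessibility of motif-containing peaks
#'
#' Pearson correlation over the shared day grid, for every (TF, peak) pair
#' where the peak contains the TF's motif and the TF is expressed.
#' Constant trajectories (either side) are dropped and counted.
#'
#' @param expr_days TFs-by-days expression matrix on the shared grid
#'   (rownames are TF names; see [matched_trajectories()]).
#' @param access_days peaks x days normalized accessibility on the same
#'   grid.
#' @param presence binary peaks x TFs motif presence matrix.
#' @param tfs TFs to evaluate (default: all rows of `expr_days` present in
#'   `presence` columns).
#' @return List with `correlations` (data.frame `tf`, `peak_id`, `r`) and
#'   `n_dropped` (constant pairs).
#' @export
correlate_tf_peaks <- function(expr_days, access_days, presence,
                               tfs = intersect(rownames(expr_days),
                                               colnames(presence))) {
  if (!identical(colnames(expr_days), colnames(access_days))) {
    stop("expression and accessibility day grids differ")
  }
  dropped <- 0L
  res <- list()
  for (tf in tfs) {
    e <- expr_days[tf, ]
    if (stats::sd(e) == 0) {
      dropped <- dropped + sum(presence[, tf] == 1)
      next
    }
    pk <- rownames(presence)[presence[, tf] == 1]
    pk <- intersect(pk, rownames(access_days))
    for (p in pk) {
      a <- access_days[p, ]
      if (stats::sd(a) == 0) {
        dropped <- dropped + 1L
        next
      }
      res[[length(res) + 1L]] <- data.frame(
        tf = tf, peak_id = p, r = stats::cor(e, a),
        stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(tf = character(), peak_id = character(), r = numeric(),
               stringsAsFactors = FALSE)
  rownames(correlations) <- NULL
  list(correlations = correlations, n_dropped = dropped)
}

#' Call activator-like / repressor-like TF behaviour
#'
#' Splits each TF's correlations by sign and compares each side against
#' the same TF's background-side distribution (by default, correlations of
#' the TF's motif-containing peaks within housekeeping TADs) with a
#' two-sided Wilcoxon rank-sum test. A TF is activator-like when the
#' median of its positive-side correlations exceeds `corr_call_threshold`
#' with p below `corr_call_p`; repressor-like is the mirror image. Sides
#' with fewer than `min_side` correlations are not called; when both sides
#' qualify, the side with more correlations wins (ties give `none`).
#'
#' The exact Wilcoxon distribution is used whenever there are no ties and
#' the product of side sizes is moderate; correlations are continuous so
#' this is the usual case.
#'
#' @param cor_fg data.frame (`tf`, `r`) of foreground correlations (e.g.
#'   peaks in EF-up TADs).
#' @param cor_bg data.frame (`tf`, `r`) of background correlations (e.g.
#'   peaks in housekeeping TADs).
#' @param thresholds an [ef_thresholds()] object.
#' @param min_side minimum correlations per side (default 5).
#' @return data.frame per TF: `tf`, `n_pos`, `n_neg`, `median_pos_r`,
#'   `median_neg_r`, `p_pos`, `p_neg`, `call`.
#' @export
call_regulators <- function(cor_fg, cor_bg,
                            thresholds = ef_thresholds(),
                            min_side = 5L) {
  out <- lapply(sort(unique(cor_fg$tf)), function(tf) {
    r <- cor_fg$r[cor_fg$tf == tf]
    rb <- cor_bg$r[cor_bg$tf == tf]
    pos <- r[r > 0]
    neg <- r[r < 0]
    bg_pos <- rb[rb > 0]
    bg_neg <- rb[rb < 0]
    p_pos <- side_test(pos, bg_pos, min_side)
    p_neg <- side_test(neg, bg_neg, min_side)
    act <- length(pos) >= min_side && length(bg_pos) >= min_side &&
      stats::median(pos) > thresholds$corr_call_threshold &&
      !is.na(p_pos) && p_pos < thresholds$corr_call_p
    rep_ <- length(neg) >= min_side && length(bg_neg) >= min_side &&
      stats::median(neg) < -thresholds$corr_call_threshold &&
      !is.na(p_neg) && p_neg < thresholds$corr_call_p
    call <- if (act && rep_) {
      if (length(pos) > length(neg)) "activator_like"
      else if (length(neg) > length(pos)) "repressor_like"
      else "none"
    } else if (act) "activator_like" else if (rep_) "repressor_like"
    else "none"
    data.frame(tf = tf, n_pos = length(pos), n_neg = length(neg),
               median_pos_r = if (length(pos)) stats::median(pos) else NA,
               median_neg_r = if (length(neg)) stats::median(neg) else NA,
               p_pos = p_pos, p_neg = p_neg, call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

side_test <- function(x, bg, min_side) {
  if (length(x) < min_side || length(bg) < min_side) return(NA_real_)
  ties <- anyDuplicated(c(x, bg)) > 0
  exact <- !ties && length(x) * length(bg) <= 40000
  suppressWarnings(
    stats::wilcox.test(x, bg, exact = exact, correct = TRUE)$p.value)
}

#' Permutation background for expression-accessibility correlations
#'
#' Second null distribution: timepoint labels of each TF's expression
#' trajectory are permuted and correlations recomputed against the same
#' peaks.
#'
#' @param expr_days,access_days,presence as in [correlate_tf_peaks()].
#' @param tfs TFs to evaluate.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return data.frame (`tf`, `r`) of null correlations.
#' @export
permutation_background <- function(expr_days, access_days, presence,
                                   tfs = intersect(rownames(expr_days),
                                                   colnames(presence)),
                                   n_perm = 1000L, seed = 1L) {
  set.seed(seed)
  d <- ncol(expr_days)
  res <- list()
  for (tf in tfs) {
    e <- expr_days[tf, ]
    if (stats::sd(e) == 0) next
    pk <- rownames(presence)[presence[, tf] == 1]
    pk <- intersect(pk, rownames(access_days))
    if (length(pk) == 0) next
    amat <- access_days[pk, , drop = FALSE]
    ok <- apply(amat, 1, stats::sd) > 0
    amat <- amat[ok, , drop = FALSE]
    if (nrow(amat) == 0) next
    for (i in seq_len(n_perm)) {
      ep <- e[sample.int(d)]
      res[[length(res) + 1L]] <- data.frame(
        tf = tf, r = as.numeric(stats::cor(ep, t(amat))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
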