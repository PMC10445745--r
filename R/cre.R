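#' Default key TF set for intra-TAD footprint-change analysis
#'
#' The canonical factors interrogated when searching a target gene's TAD
#' for candidate CREs: the core upregulated eye-field TFs plus the broadly
#' expressed co-regulators.
#'
#' @return Character vector of TF names.
#' @export
eftf_key_tfs <- function() {
  c("Rax", "Pax6", "Lhx2", "Sox2", "Otx2", "Tcf3", "Tcf7", "Tcf7l2")
}

#' Intra-TAD footprint-score change matrix for a target gene
#'
#' For every peak in the region (TAD or inter-TAD gap) containing the
#' target gene, and every key TF, the change from day A to day B in the
#' median footprint score over that TF's motif occurrences in the peak.
#' Cells without an occurrence are NA. Side columns carry the change in
#' ATAC signal and the signed distance from peak midpoint to the target
#' TSS (negative upstream of a plus-strand gene).
#'
#' @param gene target gene ID.
#' @param key_tfs TFs to include as columns (default [eftf_key_tfs()]).
#' @param dayA,dayB day labels (e.g. `"d3"`, `"d5"`).
#' @param scores data.frame from [occurrence_scores()] with added
#'   `peak_id` and `tf` columns.
#' @param peaks BED-like peak table.
#' @param peak_region named vector peak_id -> region_id (from
#'   [assign_tads()]).
#' @param gene_region named vector gene -> region_id.
#' @param genes gene-model data.frame (for TSS and strand).
#' @param access_delta named vector peak_id -> change in normalized ATAC
#'   signal between the two days.
#' @return List of class `ef_change_matrix`: `gene`, `day_pair`, `changes`
#'   (peaks x TFs matrix), `d_atac`, `tss_distance`.
#' @export
change_matrix <- function(gene, key_tfs = eftf_key_tfs(), dayA, dayB,
                          scores, peaks, peak_region, gene_region, genes,
                          access_delta) {
  region <- gene_region[[gene]]
  if (is.null(region) || is.na(region)) {
    stop(sprintf("gene '%s' has no region assignment", gene))
  }
  pk_ids <- names(peak_region)[!is.na(peak_region) & peak_region == region]
  if (length(pk_ids) == 0) {
    warning(sprintf("gene '%s': no peaks in its region", gene))
  }
  ca <- paste0("score_", dayA)
  cb <- paste0("score_", dayB)
  chg <- matrix(NA_real_, length(pk_ids), length(key_tfs),
                dimnames = list(pk_ids, key_tfs))
  for (pi in seq_along(pk_ids)) {
    for (ti in seq_along(key_tfs)) {
      sub <- scores[scores$peak_id == pk_ids[pi] &
                      scores$tf == key_tfs[ti], , drop = FALSE]
      if (nrow(sub) > 0) {
        chg[pi, ti] <- stats::median(sub[[cb]]) - stats::median(sub[[ca]])
      }
    }
  }
  gi <- match(gene, genes$gene)
  tss <- gene_tss(genes)[gi]
  pk <- peaks[match(as.character(pk_ids), as.character(peaks$peak_id)), ,
              drop = FALSE]
  mid <- (pk$start + pk$end) %/% 2L
  dist <- (mid - tss) * ifelse(genes$strand[gi] == "+", 1L, -1L)
  structure(list(gene = gene, day_pair = c(dayA, dayB), changes = chg,
                 d_atac = stats::setNames(
                   unname(access_delta[as.character(pk_ids)]), pk_ids),
                 tss_distance = stats::setNames(dist, pk_ids)),
            class = "ef_change_matrix")
}

#' Rank candidate cis-regulatory elements for a target gene
#'
#' Each peak is scored by the sum of positive footprint-score changes over
#' the key TFs (absent cells contribute 0); ties are broken by larger
#' change in ATAC signal, then by proximity to the target TSS.
#'
#' @param cm an `ef_change_matrix` from [change_matrix()].
#' @return data.frame of peaks in descending rank order: `rank`,
#'   `peak_id`, `score`, `d_atac`, `tss_distance`.
#' @export
rank_candidates <- function(cm) {
  if (nrow(cm$changes) == 0) stop("empty change matrix")
  score <- apply(cm$changes, 1, function(v) sum(pmax(v, 0), na.rm = TRUE))
  o <- order(-score, -cm$d_atac, abs(cm$tss_distance))
  data.frame(rank = seq_along(o), peak_id = rownames(cm$changes)[o],
             gene = cm$gene, score = score[o],
             d_atac = cm$d_atac[o], tss_distance = cm$tss_distance[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deletion interval covering selected motif occurrences
#'
#' The minimal interval containing all selected occurrences, padded by
#' `pad` bp on each side and clipped to the host peak. The interval length
#' is `end - start` (half-open convention).
#'
#' @param peak single-row BED-like peak (with `chrom`, `start`, `end`).
#' @param occs occurrences to cover (`start`, `end`, genomic, within the
#'   peak).
#' @param pad bp of padding either side (default 10).
#' @return List with `chrom`, `start`, `end`, `length`, `clipped`.
#' @export
deletion_interval <- function(peak, occs, pad = 10L) {
  if (nrow(occs) == 0) stop("no occurrences selected")
  if (any(occs$start < peak$start | occs$end > peak$end)) {
    stop("occurrences must lie within the peak")
  }
  raw_start <- min(occs$start) - pad
  raw_end <- max(occs$end) + pad
  start <- max(raw_start, peak$start)
  end <- min(raw_end, peak$end)
  clipped <- raw_start < peak$start || raw_end > peak$end
  if (clipped) message("deletion interval clipped to peak bounds")
  list(chrom = peak$chrom, start = start, end = end,
       length = interval_length(start, end), clipped = clipped)
}

#' Compare wild-type and perturbed expression
#'
#' Welch's unequal-variance two-sided t-test on replicate log2 expression,
#' plus the percent change of mean log2 expression,
#' `100 * (mean_ko - mean_wt) / mean_wt`.
#'
#' @param expr_wt,expr_ko numeric vectors of replicate log2 expression
#'   values (>= 3 each).
#' @return List with `mean_log2_wt`, `mean_log2_ko`, `pct_change_log2`,
#'   `p`.
#' @export
perturbation_compare <- function(expr_wt, expr_ko) {
  if (length(expr_wt) < 3 || length(expr_ko) < 3) {
    stop("need >= 3 replicates per arm")
  }
  m_wt <- mean(expr_wt)
  m_ko <- mean(expr_ko)
  p <- if (stats::var(expr_wt) == 0 && stats::var(expr_ko) == 0) {
    if (m_wt == m_ko) 1 else 0
  } else {
    stats::t.test(expr_wt, expr_ko)$p.value
  }
  list(mean_log2_wt = m_wt, mean_log2_ko = m_ko,
       pct_change_log2 = 100 * (m_ko - m_wt) / m_wt, p = p)
}
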