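#' Run the full analysis pipeline on a simulated bundle
#'
#' Executes every stage in order: normalization and differential
#' expression, EF-up/EF-down/housekeeping gating, accessibility
#' normalization and dynamic-peak calling, peak annotation and TAD/gap
#' assignment, motif scanning and TF-level presence, motif enrichment,
#' the logistic motif-importance model on genome-wide dynamic peaks,
#' expression-accessibility correlation with regulator calls,
#' occurrence-level footprint scores with differential binding and
#' footprint-expression correlation, and candidate-CRE ranking for each
#' inter-TAD target gene.
#'
#' The key TF panel for CRE prioritization is an a-priori input (as a
#' fixed set of canonical factors would be); by default the planted
#' activator TFs are used.
#'
#' @param bundle output of [simulate_bundle()].
#' @param thresholds an [ef_thresholds()] object.
#' @param seed seed for the stochastic stages (CV folds, GMM inits).
#' @param key_tfs TF panel for the intra-TAD change matrices (default:
#'   the bundle's activator TFs).
#' @param cluster also run trajectory clustering (default FALSE; the
#'   clustering stage is exercised separately).
#' @param logit_min_per_class minimum dynamic peaks per class required by
#'   the logistic model (default 20; lower it for very small simulated
#'   genomes).
#' @return A list with the outputs of every stage (see element names).
#' @export
run_pipeline <- function(bundle, thresholds = ef_thresholds(), seed = 1L,
                         key_tfs = NULL, cluster = FALSE,
                         logit_min_per_class = 20L) {
  genome <- bundle$genome
  truth <- bundle$truth
  counts <- bundle$counts
  meta <- counts$meta
  ## expression
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  grp <- function(day, gfp = "unsorted") {
    meta$sample_id[meta$day == day & meta$gfp == gfp]
  }
  de <- list(
    d3_vs_d4p = differential_expression(norm, grp(3), grp(4, "positive")),
    d4n_vs_d4p = differential_expression(norm, grp(4, "negative"),
                                         grp(4, "positive")),
    d5n_vs_d5p = differential_expression(norm, grp(5, "negative"),
                                         grp(5, "positive")))
  gene_sets <- call_ef_genes(de, thresholds)
  hk <- housekeeping_genes(norm, meta, thresholds)
  gene_sets$housekeeping <- setdiff(hk, c(gene_sets$ef_up,
                                          gene_sets$ef_down))
  ## accessibility
  peaks <- genome$peaks
  seqs <- truth$sequences[as.character(peaks$peak_id)]
  acc_norm <- normalize_accessibility(bundle$access$signal,
                                      gc = gc_content(seqs),
                                      width = peaks$end - peaks$start)
  dyn <- dynamic_peaks(acc_norm, "d3", "d5", thresholds$atac_dynamic_lfc)
  dyn_model <- dynamic_peaks(acc_norm, "d3", "d5",
                             thresholds$model_dynamic_lfc)
  annotation <- annotate_peaks(peaks, genome$genes,
                               thresholds$promoter_window)
  tad_assign <- assign_tads(genome$tads, peaks, genome$genes, gene_sets)
  dyn_sel <- dyn$dynamic_class != "static"
  nonpromoter_fraction <-
    if (any(dyn_sel)) mean(annotation[dyn_sel] != "promoter") else NA_real_
  prom_idx <- annotation == "promoter"
  dyn_nonprom <- dyn_sel & !prom_idx
  prom_stats <- if (sum(prom_idx) >= 2 && sum(dyn_nonprom) >= 2) {
    promoter_stats(acc_norm[prom_idx, , drop = FALSE],
                   acc_norm[dyn_nonprom, , drop = FALSE])
  } else NULL
  ## motifs
  occurrences <- scan_motifs(truth$motifs, seqs,
                             p_thresh = thresholds$motif_pvalue)
  expressed <- expressed_tfs(norm, meta, truth$tf_genes, thresholds)
  presence <- motif_presence(occurrences, as.character(peaks$peak_id),
                             tfs = expressed)
  region_class <- tad_assign$regions$class[
    match(tad_assign$peak_region, tad_assign$regions$region_id)]
  names(region_class) <- names(tad_assign$peak_region)
  hk_peaks <- names(region_class)[!is.na(region_class) &
                                    region_class == "housekeeping"]
  opening_ids <- as.character(dyn$peak_id[dyn$dynamic_class == "opening"])
  closing_ids <- as.character(dyn$peak_id[dyn$dynamic_class == "closing"])
  non_exonic <- as.character(peaks$peak_id)[annotation != "exonic"]
  enrichment <- list(
    opening = motif_enrichment(presence, intersect(opening_ids, non_exonic),
                               hk_peaks),
    closing = motif_enrichment(presence, intersect(closing_ids, non_exonic),
                               hk_peaks))
  model_ids <- as.character(
    dyn_model$peak_id[dyn_model$dynamic_class != "static"])
  logit <- fit_motif_logit(
    presence[model_ids, , drop = FALSE],
    labels = dyn_model$dynamic_class[match(model_ids,
                                           as.character(dyn_model$peak_id))],
    thresholds = thresholds, seed = seed,
    min_per_class = logit_min_per_class)
  ## expression-accessibility correlation
  expr_days <- matched_trajectories(norm, meta)
  expr_tfs <- expr_days[truth$tf_genes[expressed], , drop = FALSE]
  rownames(expr_tfs) <- expressed
  fg_peaks <- names(region_class)[!is.na(region_class) &
                                    grepl("ef_up", region_class)]
  corr_fg <- correlate_tf_peaks(expr_tfs, acc_norm[fg_peaks, , drop = FALSE],
                                presence[fg_peaks, , drop = FALSE])
  corr_bg <- correlate_tf_peaks(expr_tfs, acc_norm[hk_peaks, , drop = FALSE],
                                presence[hk_peaks, , drop = FALSE])
  calls <- call_regulators(corr_fg$correlations, corr_bg$correlations,
                           thresholds)
  ## footprinting
  occ_g <- occurrences
  pidx <- match(occ_g$peak_id, as.character(peaks$peak_id))
  occ_g$chrom <- peaks$chrom[pidx]
  occ_g$start <- peaks$start[pidx] + occ_g$offset
  occ_g$end <- occ_g$start + occ_g$width
  scores <- occurrence_scores(bundle$access$tracks, occ_g,
                              central_halfwidth = thresholds$fp_central_halfwidth,
                              flank_width = thresholds$fp_flank_width)
  scores$peak_id <- occ_g$peak_id
  scores$tf <- occ_g$tf
  diff_bind <- differential_binding(scores, "d3", "d5")
  mtf <- motif_tfs(truth$motifs)
  fp_corr_fg <- footprint_expression_correlation(
    scores, mtf, expr_tfs, subset = scores$peak_id %in% fg_peaks)
  fp_corr_all <- footprint_expression_correlation(scores, mtf, expr_tfs)
  ## CRE prioritization for gap target genes
  if (is.null(key_tfs)) {
    key_tfs <- names(truth$tf_role)[truth$tf_role == "activator"]
  }
  access_delta <- stats::setNames(dyn$delta, as.character(dyn$peak_id))
  candidates <- list()
  for (gene in genome$gap_genes) {
    cm <- change_matrix(gene, key_tfs = key_tfs, dayA = "d3", dayB = "d5",
                        scores = scores, peaks = peaks,
                        peak_region = tad_assign$peak_region,
                        gene_region = tad_assign$gene_region,
                        genes = genome$genes, access_delta = access_delta)
    candidates[[gene]] <- rank_candidates(cm)
  }
  clustering <- NULL
  if (cluster) {
    ef_genes <- c(gene_sets$ef_up, gene_sets$ef_down)
    dm <- day_mean_matrix(norm, meta)
    clustering <- cluster_trajectories(dm[ef_genes, , drop = FALSE],
                                       n_init = thresholds$gmm_n_init,
                                       seed = seed)
  }
  list(size_factors = sf, norm = norm, de = de, gene_sets = gene_sets,
       acc_norm = acc_norm, dynamic = dyn, dynamic_model = dyn_model,
       annotation = annotation, tad_assign = tad_assign,
       nonpromoter_fraction = nonpromoter_fraction,
       promoter_stats = prom_stats,
       region_class = region_class, occurrences = occurrences,
       expressed_tfs = expressed, presence = presence,
       enrichment = enrichment, logit = logit, expr_tfs = expr_tfs,
       corr_fg = corr_fg, corr_bg = corr_bg, regulator_calls = calls,
       scores = scores, diff_bind = diff_bind,
       fp_corr_fg = fp_corr_fg, fp_corr_all = fp_corr_all,
       candidates = candidates, clustering = clustering)
}

#' Recovery metrics of a pipeline run against planted truth
#'
#' @param bundle the simulated bundle.
#' @param res output of [run_pipeline()] on that bundle.
#' @return Named list: EF gene recall/precision, opening-peak recall,
#'   fraction of activator (repressor) TFs whose logistic coefficient
#'   lies in the top (bottom) quartile, per-TF median
#'   expression-accessibility correlations in EF-up regions, and the rank
#'   of each planted CRE.
#' @export
evaluate_recovery <- function(bundle, res) {
  truth <- bundle$truth
  truth_up <- names(truth$gene_programme)[
    truth$gene_programme == "up_after_d3"]
  truth_down <- names(truth$gene_programme)[
    truth$gene_programme %in% c("gradual_down", "transient")]
  pr <- function(pred, tru) {
    list(recall = if (length(tru)) mean(tru %in% pred) else NA,
         precision = if (length(pred)) mean(pred %in% tru) else NA)
  }
  up <- pr(res$gene_sets$ef_up, truth_up)
  down <- pr(res$gene_sets$ef_down, truth_down)
  truth_open <- names(truth$peak_class)[truth$peak_class == "opening"]
  pred_open <- as.character(
    res$dynamic$peak_id[res$dynamic$dynamic_class == "opening"])
  opening_recall <- mean(truth_open %in% pred_open)
  cf <- sort(res$logit$coefficients, decreasing = TRUE)
  n_q <- ceiling(length(cf) / 4)
  acts <- names(truth$tf_role)[truth$tf_role == "activator"]
  reps <- names(truth$tf_role)[truth$tf_role == "repressor"]
  act_top <- mean(acts %in% names(cf)[seq_len(n_q)])
  rep_bottom <- mean(reps %in% names(cf)[(length(cf) - n_q + 1):length(cf)])
  med_r <- function(tfs) {
    vapply(tfs, function(tf) {
      r <- res$corr_fg$correlations$r[res$corr_fg$correlations$tf == tf]
      if (length(r)) stats::median(r) else NA_real_
    }, 1.0)
  }
  cre_rank <- vapply(names(truth$cre), function(g) {
    rk <- res$candidates[[g]]
    if (is.null(rk)) return(NA_real_)
    as.numeric(rk$rank[match(truth$cre[[g]], rk$peak_id)])
  }, 1.0)
  list(ef_up_recall = up$recall, ef_up_precision = up$precision,
       ef_down_recall = down$recall, ef_down_precision = down$precision,
       opening_recall = opening_recall,
       activator_top_quartile = act_top,
       repressor_bottom_quartile = rep_bottom,
       activator_median_corr = med_r(acts),
       repressor_median_corr = med_r(reps),
       cre_rank = cre_rank)
}

#' Quick planted-CRE rank check for one seed
#'
#' Simulates a bundle, scores only the occurrences inside the inter-TAD
#' target regions, and returns the rank of each planted CRE for its
#' target gene. Used to assess CRE-prioritization stability across
#' simulation seeds without rerunning the full pipeline.
#'
#' @param seed simulation seed.
#' @param preset passed to [simulate_bundle()].
#' @param thresholds an [ef_thresholds()] object.
#' @return Named numeric vector of CRE ranks (1 = top) per target gene.
#' @export
cre_rank_check <- function(seed, preset = "default",
                           thresholds = ef_thresholds()) {
  bundle <- simulate_bundle(preset, seed = seed)
  genome <- bundle$genome
  truth <- bundle$truth
  peaks <- genome$peaks
  gene_sets <- list(ef_up = character(0), ef_down = character(0),
                    housekeeping = character(0))
  tad_assign <- assign_tads(genome$tads, peaks, genome$genes, gene_sets)
  target_regions <- tad_assign$gene_region[genome$gap_genes]
  pk_ids <- names(tad_assign$peak_region)[
    tad_assign$peak_region %in% target_regions]
  seqs <- truth$sequences[pk_ids]
  key_tfs <- names(truth$tf_role)[truth$tf_role == "activator"]
  key_motifs <- structure(
    truth$motifs[motif_tfs(truth$motifs) %in% key_tfs],
    class = "ef_motifs")
  occurrences <- scan_motifs(key_motifs, seqs,
                             p_thresh = thresholds$motif_pvalue)
  pidx <- match(occurrences$peak_id, as.character(peaks$peak_id))
  occurrences$chrom <- peaks$chrom[pidx]
  occurrences$start <- peaks$start[pidx] + occurrences$offset
  occurrences$end <- occurrences$start + occurrences$width
  scores <- occurrence_scores(bundle$access$tracks, occurrences,
                              central_halfwidth = thresholds$fp_central_halfwidth,
                              flank_width = thresholds$fp_flank_width)
  scores$peak_id <- occurrences$peak_id
  scores$tf <- occurrences$tf
  seqs_all <- truth$sequences[as.character(peaks$peak_id)]
  acc_norm <- normalize_accessibility(bundle$access$signal,
                                      gc = gc_content(seqs_all),
                                      width = peaks$end - peaks$start)
  dyn <- dynamic_peaks(acc_norm, "d3", "d5", thresholds$atac_dynamic_lfc)
  access_delta <- stats::setNames(dyn$delta, as.character(dyn$peak_id))
  vapply(genome$gap_genes, function(gene) {
    cm <- change_matrix(gene, key_tfs = key_tfs, dayA = "d3", dayB = "d5",
                        scores = scores, peaks = peaks,
                        peak_region = tad_assign$peak_region,
                        gene_region = tad_assign$gene_region,
                        genes = genome$genes, access_delta = access_delta)
    rk <- rank_candidates(cm)
    as.numeric(rk$rank[match(truth$cre[[gene]], rk$peak_id)])
  }, 1.0)
}
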