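#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio
#' of that sample's count to the gene's geometric mean across samples,
#' computed over genes with nonzero counts in every sample. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts an `ef_counts` object or count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  mat <- if (inherits(counts, "ef_counts")) counts$counts else as.matrix(counts)
  use <- rowSums(mat == 0) == 0
  if (!any(use)) {
    stop("no gene has nonzero counts in all samples; ",
         "add a pseudocount before computing size factors")
  }
  logmat <- log(mat[use, , drop = FALSE])
  loggeo <- rowMeans(logmat)
  f <- apply(logmat, 2, function(col) exp(stats::median(col - loggeo)))
  f <- f / exp(mean(log(f)))
  f
}

#' Normalize counts by size factors
#'
#' @param counts an `ef_counts` object or count matrix.
#' @param factors optional size factors; computed by [size_factors()] when
#'   missing.
#' @return Matrix of normalized counts (count / size factor).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  mat <- if (inherits(counts, "ef_counts")) counts$counts else as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(mat)
  sweep(mat, 2, factors, "/")
}

#' Differential expression between two sample groups
#'
#' log2 fold change is computed on group means of normalized counts with a
#' pseudocount. p-values come from one of two engines applied to
#' log2(normalized + pseudocount) replicate values: the default,
#' `"moderated"`, is an empirical-Bayes moderated t (limma with a
#' mean-variance trend), which pools variance information across genes and
#' so remains calibrated with few replicates; `"welch"` is a per-gene
#' Welch t-test. FDR by Benjamini-Hochberg across all genes tested. Genes
#' with zero variance in both groups and equal means get p = 1.
#'
#' @param norm matrix of normalized counts (genes x samples).
#' @param groupA,groupB character vectors of sample IDs (columns of `norm`);
#'   the reported fold change is B versus A.
#' @param pseudocount added before taking logs (default 1).
#' @param engine `"moderated"` (default) or `"welch"`.
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#' @export
differential_expression <- function(norm, groupA, groupB, pseudocount = 1,
                                    engine = c("moderated", "welch")) {
  engine <- match.arg(engine)
  missing <- setdiff(c(groupA, groupB), colnames(norm))
  if (length(missing) > 0) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  }
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs >= 2 replicates")
  }
  a <- norm[, groupA, drop = FALSE]
  b <- norm[, groupB, drop = FALSE]
  log2fc <- log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  if (engine == "moderated") {
    design <- cbind(intercept = 1,
                    groupB = rep(c(0, 1), c(length(groupA), length(groupB))))
    fit <- limma::lmFit(cbind(la, lb), design)
    fit <- limma::eBayes(fit, trend = nrow(norm) >= 10)
    pvalue <- fit$p.value[, "groupB"]
    # degenerate all-equal genes: a 0/0 statistic yields NaN
    pvalue[is.na(pvalue)] <- 1
  } else {
    pvalue <- vapply(seq_len(nrow(norm)), function(i) {
      xa <- la[i, ]
      xb <- lb[i, ]
      if (stats::var(xa) == 0 && stats::var(xb) == 0) {
        return(if (mean(xa) == mean(xb)) 1 else 0)
      }
      stats::t.test(xb, xa)$p.value
    }, 1.0)
  }
  data.frame(gene = rownames(norm), log2fc = log2fc, pvalue = unname(pvalue),
             fdr = stats::p.adjust(pvalue, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gate EF-up and EF-down gene sets from the transition contrasts
#'
#' A gene is EF-up if it passes `fdr < de_fdr` and `log2fc > de_lfc`
#' (strictly) in every supplied contrast; EF-down analogously with
#' `log2fc < -de_lfc`. The canonical contrasts are day 3 vs day-4 GFP+,
#' day-4 GFP- vs GFP+, and day-5 GFP- vs GFP+ (fold changes oriented
#' towards the GFP-positive lineage).
#'
#' @param de_tables named list of data.frames from
#'   [differential_expression()], all over the same gene universe.
#' @param thresholds an [ef_thresholds()] object.
#' @return List with character vectors `ef_up` and `ef_down`.
#' @export
call_ef_genes <- function(de_tables, thresholds = ef_thresholds()) {
  if (length(de_tables) < 1) stop("missing contrast tables")
  genes <- de_tables[[1]]$gene
  for (tab in de_tables) {
    if (!identical(sort(tab$gene), sort(genes))) {
      stop("contrast tables cover different gene universes")
    }
  }
  up <- rep(TRUE, length(genes))
  down <- rep(TRUE, length(genes))
  names(up) <- names(down) <- genes
  for (tab in de_tables) {
    idx <- match(genes, tab$gene)
    sig <- tab$fdr[idx] < thresholds$de_fdr
    up <- up & sig & (tab$log2fc[idx] > thresholds$de_lfc)
    down <- down & sig & (tab$log2fc[idx] < -thresholds$de_lfc)
  }
  list(ef_up = genes[up], ef_down = genes[down])
}

#' Stably expressed (housekeeping) genes
#'
#' Genes whose replicate-mean normalized expression changes by less than
#' `hk_lfc` in absolute log2 fold change between every pair of successive
#' days, and whose mean expression across days exceeds `hk_min_expr`. Days 4
#' and 5 use the GFP-positive branch (the lineage under study).
#'
#' @param norm matrix of normalized counts.
#' @param meta sample metadata (as in `ef_counts$meta`).
#' @param thresholds an [ef_thresholds()] object.
#' @return Character vector of housekeeping gene IDs.
#' @export
housekeeping_genes <- function(norm, meta, thresholds = ef_thresholds()) {
  day_means <- day_mean_matrix(norm, meta)
  lfc <- log2(day_means[, -1, drop = FALSE] + 1) -
    log2(day_means[, -ncol(day_means), drop = FALSE] + 1)
  ok_flat <- apply(abs(lfc) < thresholds$hk_lfc, 1, all)
  ok_expr <- rowMeans(day_means) > thresholds$hk_min_expr
  rownames(norm)[ok_flat & ok_expr]
}

# Replicate-mean expression per day, GFP+ branch at days >= 4.
day_mean_matrix <- function(norm, meta, days = 0:5) {
  cols <- lapply(days, function(d) {
    sel <- meta$day == d & (meta$gfp %in% c("unsorted", "positive"))
    if (d >= 4) sel <- meta$day == d & meta$gfp == "positive"
    meta$sample_id[sel]
  })
  present <- vapply(cols, length, 1L) > 0
  out <- matrix(0, nrow(norm), sum(present),
                dimnames = list(rownames(norm),
                                paste0("d", days[present])))
  for (j in seq_len(sum(present))) {
    out[, j] <- rowMeans(norm[, cols[present][[j]], drop = FALSE])
  }
  out
}

#' Overlap between two gene sets
#'
#' @param setA,setB character vectors.
#' @return List with `n_a`, `n_b`, `n_overlap` and the overlapping genes.
#' @export
stage_overlap <- function(setA, setB) {
  ov <- intersect(setA, setB)
  list(n_a = length(unique(setA)), n_b = length(unique(setB)),
       n_overlap = length(ov), overlap = ov)
}
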