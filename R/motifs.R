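BASES <- c("A", "C", "G", "T")

#' Log-odds position weight matrix from a PFM
#'
#' @param pfm 4 x width count matrix (rows A,C,G,T).
#' @param pseudocount added to every cell before normalization (default
#'   0.1).
#' @param background base frequencies (A,C,G,T), default uniform.
#' @return 4 x width matrix of log2 likelihood ratios.
#' @export
pwm_from_pfm <- function(pfm, pseudocount = 0.1,
                         background = rep(0.25, 4)) {
  probs <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  log2(sweep(probs, 1, background, "/"))
}

# Integer-rounded score representation of a PWM: per-column offsets are
# removed and scores scaled so the total attainable range spans ~n_bins
# integer steps. The exact null score distribution is then a DP over
# columns.
pwm_integerize <- function(pwm, n_bins = 1000L) {
  mins <- apply(pwm, 2, min)
  shifted <- sweep(pwm, 2, mins, "-")
  rng <- sum(apply(shifted, 2, max))
  scale <- if (rng > 0) n_bins / rng else 1
  list(imat = round(shifted * scale), scale = scale, mins = mins)
}

#' Exact PWM score p-values by dynamic programming
#'
#' Computes the null distribution of the integer-rounded PWM score under
#' i.i.d. background base frequencies (the FIMO approach), and returns the
#' upper-tail p-value for every attainable integer score.
#'
#' @param pwm 4 x width log-odds matrix.
#' @param background base frequencies (A,C,G,T).
#' @param n_bins granularity of the integer rounding (default 1000).
#' @return List with `pvals` (vector; `pvals[s + 1]` is P(score >= s)),
#'   `imat` (integer score matrix) and `scale`.
#' @export
pwm_score_pvalues <- function(pwm, background = rep(0.25, 4),
                              n_bins = 1000L) {
  iz <- pwm_integerize(pwm, n_bins)
  imat <- iz$imat
  max_total <- sum(apply(imat, 2, max))
  pdf <- numeric(max_total + 1)
  pdf[1] <- 1
  for (j in seq_len(ncol(imat))) {
    new <- numeric(max_total + 1)
    for (b in 1:4) {
      s <- imat[b, j]
      nz <- which(pdf != 0)
      new[nz + s] <- new[nz + s] + pdf[nz] * background[b]
    }
    pdf <- new
  }
  pvals <- rev(cumsum(rev(pdf)))
  list(pvals = pvals, imat = imat, scale = iz$scale)
}

encode_seq <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], BASES)
  v  # N and other ambiguity codes become NA; windows containing NA skipped
}

revcomp_pwm <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- BASES
  out
}

score_positions <- function(enc, mat) {
  w <- ncol(mat)
  L <- length(enc)
  if (L < w) return(numeric(0))
  npos <- L - w + 1L
  sc <- numeric(npos)
  for (j in seq_len(w)) {
    sc <- sc + mat[cbind(enc[j:(L - w + j)], rep(j, npos))]
  }
  sc
}

#' Scan sequences for significant motif occurrences
#'
#' FIMO-style scan: both strands are scored at every position, the best
#' strand per position is reported (ties to `+`), and occurrences are kept
#' when the exact upper-tail p-value of the integer-rounded score is at
#' most `p_thresh`. Windows containing non-ACGT characters are skipped.
#'
#' @param motifs an `ef_motifs` object.
#' @param seqs named character vector of peak sequences; names are used as
#'   `peak_id`.
#' @param background base frequencies (A,C,G,T), default uniform.
#' @param p_thresh occurrence p-value threshold (default 1e-4).
#' @param pseudocount PFM pseudocount (default 0.1).
#' @return data.frame of occurrences: `peak_id`, `motif_id`, `tf`,
#'   `offset` (0-based from sequence start), `strand`, `llr_score`,
#'   `pvalue`.
#' @export
scan_motifs <- function(motifs, seqs, background = rep(0.25, 4),
                        p_thresh = 1e-4, pseudocount = 0.1) {
  enc_list <- lapply(seqs, encode_seq)
  res <- list()
  for (m in motifs) {
    pwm <- pwm_from_pfm(m$pfm, pseudocount, background)
    dp <- pwm_score_pvalues(pwm, background)
    w <- ncol(pwm)
    # integer score of the reverse strand uses the same column offsets,
    # reversed, so the null distribution (hence p-values) is shared
    imat_rc <- dp$imat[4:1, rev(seq_len(w)), drop = FALSE]
    rownames(imat_rc) <- BASES
    for (sn in names(enc_list)) {
      enc <- enc_list[[sn]]
      if (length(enc) < w) next
      na_pos <- is.na(enc)
      enc2 <- ifelse(na_pos, 1L, enc)
      fwd <- score_positions(enc2, dp$imat)
      rev_ <- score_positions(enc2, imat_rc)
      # invalidate windows containing N
      if (any(na_pos)) {
        bad <- which(stats::filter(as.numeric(na_pos), rep(1, w),
                                   sides = 1)[w:length(enc)] > 0)
        fwd[bad] <- rev_[bad] <- -1
      }
      strand <- ifelse(fwd >= rev_, "+", "-")
      best <- pmax(fwd, rev_)
      pv <- ifelse(best >= 0, dp$pvals[best + 1L], 1)
      keep <- which(pv <= p_thresh)
      if (length(keep) == 0) next
      # report the real log-likelihood-ratio score of the reported strand
      pwm_rc <- revcomp_pwm(pwm)
      llr <- vapply(keep, function(k) {
        win <- enc2[k:(k + w - 1L)]
        mat <- if (strand[k] == "+") pwm else pwm_rc
        sum(mat[cbind(win, seq_len(w))])
      }, 1.0)
      res[[length(res) + 1L]] <- data.frame(
        peak_id = sn, motif_id = m$id, tf = m$tf, offset = keep - 1L,
        strand = strand[keep], llr_score = llr, pvalue = pv[keep],
        width = w, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(peak_id = character(), motif_id = character(),
                      tf = character(), offset = integer(),
                      strand = character(), llr_score = numeric(),
                      pvalue = numeric(), width = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' TF-level motif presence matrix
#'
#' A TF motif is present in a peak when the peak contains a significant
#' occurrence of any of the TF's motifs.
#'
#' @param occurrences data.frame from [scan_motifs()].
#' @param peak_ids character vector defining the row universe.
#' @param tfs optional character vector defining the column universe
#'   (default: TFs seen in `occurrences`).
#' @return Binary matrix, peaks x TFs.
#' @export
motif_presence <- function(occurrences, peak_ids, tfs = NULL) {
  if (is.null(tfs)) tfs <- sort(unique(occurrences$tf))
  out <- matrix(0L, length(peak_ids), length(tfs),
                dimnames = list(peak_ids, tfs))
  occ <- occurrences[occurrences$peak_id %in% peak_ids &
                       occurrences$tf %in% tfs, , drop = FALSE]
  if (nrow(occ) > 0) {
    out[cbind(match(occ$peak_id, peak_ids), match(occ$tf, tfs))] <- 1L
  }
  out
}

#' Expressed transcription factors
#'
#' A TF counts as expressed when its replicate-mean normalized expression
#' exceeds `tf_expr_min` (strictly) at one or more timepoints (any GFP
#' branch).
#'
#' @param norm normalized expression matrix.
#' @param meta sample metadata.
#' @param tf_genes named character vector mapping TF name to gene ID.
#' @param thresholds an [ef_thresholds()] object.
#' @return Character vector of expressed TF names.
#' @export
expressed_tfs <- function(norm, meta, tf_genes,
                          thresholds = ef_thresholds()) {
  known <- tf_genes[tf_genes %in% rownames(norm)]
  if (length(known) < length(tf_genes)) {
    warning("TF(s) without expression record excluded: ",
            paste(names(tf_genes)[!tf_genes %in% rownames(norm)],
                  collapse = ", "))
  }
  groups <- split(meta$sample_id, paste(meta$day, meta$gfp))
  gm <- vapply(groups, function(ids) {
    rowMeans(norm[known, ids, drop = FALSE])
  }, numeric(length(known)))
  if (length(known) == 1) gm <- matrix(gm, nrow = 1)
  expressed <- apply(gm, 1, function(v) any(v > thresholds$tf_expr_min))
  names(known)[expressed]
}

#' Motif enrichment against a background peak set
#'
#' One-sided (over-representation) hypergeometric test of TF motif
#' presence in a signal peak set against a background set (signal peaks
#' are removed from the background first). Odds ratios use the Haldane
#' +0.5 correction when a cell is zero.
#'
#' @param presence binary peaks x TFs matrix covering both sets.
#' @param signal_peaks,background_peaks character vectors of peak IDs
#'   (rows of `presence`).
#' @return data.frame with `tf`, `odds_ratio`, `pvalue` and the 2x2
#'   counts.
#' @export
motif_enrichment <- function(presence, signal_peaks, background_peaks) {
  background_peaks <- setdiff(background_peaks, signal_peaks)
  if (length(background_peaks) == 0) stop("empty background peak set")
  sig <- presence[as.character(signal_peaks), , drop = FALSE]
  bg <- presence[as.character(background_peaks), , drop = FALSE]
  n_sig <- nrow(sig)
  n_bg <- nrow(bg)
  out <- lapply(colnames(presence), function(tf) {
    a <- sum(sig[, tf])          # signal, present
    b <- n_sig - a               # signal, absent
    c_ <- sum(bg[, tf])          # background, present
    d <- n_bg - c_
    p <- stats::phyper(a - 1, a + c_, b + d, n_sig, lower.tail = FALSE)
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    data.frame(tf = tf, odds_ratio = (cells[1] * cells[4]) /
                 (cells[2] * cells[3]),
               pvalue = p, signal_present = a, signal_absent = b,
               background_present = c_, background_absent = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' L2-regularized logistic motif-importance model
#'
#' Predicts opening versus closing peak behaviour from TF motif presence.
#' The regularization strength is chosen on a log-spaced grid by mean
#' held-out log-loss over stratified cross-validation (class imbalance
#' handled by class weights); final coefficients are the mean over
#' `n_seeds` refits on all peaks. Positive coefficients predict opening.
#'
#' @param presence binary peaks x TFs matrix (restricted to feature TFs).
#' @param labels character/factor vector per peak, values `opening` /
#'   `closing`.
#' @param thresholds an [ef_thresholds()] object (CV folds, refit seeds).
#' @param seed master seed for fold assignment.
#' @param lambda_grid regularization grid (default 13 log-spaced values in
#'   `[1e-3, 1e3]`).
#' @param min_per_class minimum peaks required per class (default 20).
#' @return List with `coefficients` (named, intercept excluded), `lambda`,
#'   and `auc_cv` (held-out AUC at the chosen lambda).
#' @export
fit_motif_logit <- function(presence, labels,
                            thresholds = ef_thresholds(), seed = 1L,
                            lambda_grid = 10^seq(3, -3, length.out = 13),
                            min_per_class = 20L) {
  y <- as.integer(as.character(labels) == "opening")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < min_per_class) {
    stop(sprintf("need >= %d peaks per class", min_per_class))
  }
  x <- as.matrix(presence)
  n <- length(y)
  wts <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  k <- thresholds$logit_cv_folds
  set.seed(seed)
  folds <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  loss <- matrix(NA_real_, k, length(lambda_grid))
  auc_parts <- matrix(NA_real_, k, length(lambda_grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 0,
                          lambda = lambda_grid, weights = wts[tr],
                          standardize = FALSE)
    pr <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response")
    yo <- y[!tr]
    for (li in seq_len(ncol(pr))) {
      p <- pmin(pmax(pr[, li], 1e-12), 1 - 1e-12)
      loss[f, li] <- -mean(yo * log(p) + (1 - yo) * log(1 - p))
      auc_parts[f, li] <- rank_auc(p, yo)
    }
  }
  mean_loss <- colMeans(loss)
  li_best <- which.min(mean_loss)
  lambda <- lambda_grid[li_best]
  # the objective is convex, so seeded refits coincide; the averaging loop
  # is kept to match the stated fitting protocol
  coefs <- matrix(0, ncol(x), thresholds$logit_n_seeds)
  for (s in seq_len(thresholds$logit_n_seeds)) {
    set.seed(seed + s)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda_grid, weights = wts,
                          standardize = FALSE)
    coefs[, s] <- as.numeric(stats::coef(fit, s = lambda))[-1]
  }
  cf <- rowMeans(coefs)
  names(cf) <- colnames(x)
  list(coefficients = cf, lambda = lambda,
       auc_cv = mean(auc_parts[, li_best], na.rm = TRUE))
}

rank_auc <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
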