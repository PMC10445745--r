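#' Aggregate footprint profile around motif occurrences
#'
#' Positionwise mean of corrected per-bp signal in windows spanning each
#' occurrence plus `halfwidth` bp either side (window length = motif width
#' + 2 x halfwidth, centre-aligned). Minus-strand windows are reversed
#' before averaging so footprint asymmetries align. Occurrences whose
#' window extends beyond the stored chromosome are skipped and counted.
#'
#' @param track an `ef_track` of corrected signal.
#' @param occs data.frame of same-width occurrences with `chrom`, `start`,
#'   `end` (0-based half-open genomic coordinates) and `strand`.
#' @param halfwidth window extension either side (default 100).
#' @return List with `values` (mean profile), `n_occurrences`, `width`
#'   (motif width) and `n_skipped`.
#' @export
aggregate_profile <- function(track, occs, halfwidth = 100L) {
  w <- unique(occs$end - occs$start)
  if (length(w) != 1) stop("occurrences must share one motif width")
  acc <- NULL
  n <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(occs))) {
    ws <- occs$start[i] - halfwidth
    we <- occs$end[i] + halfwidth
    chrom_len <- length(track$values[[occs$chrom[i]]])
    if (is.null(track$values[[occs$chrom[i]]]) || ws < 0 || we > chrom_len) {
      skipped <- skipped + 1L
      next
    }
    v <- track_query(track, occs$chrom[i], ws, we)
    if (occs$strand[i] == "-") v <- rev(v)
    acc <- if (is.null(acc)) v else acc + v
    n <- n + 1L
  }
  if (n == 0) stop("no usable occurrences")
  list(values = acc / n, n_occurrences = n, width = w,
       n_skipped = skipped)
}

#' Footprint depth and flanking accessibility
#'
#' The central region is the 2 x `central_halfwidth` bp window around the
#' motif centre; flanking accessibility is the mean signal over the
#' `flank_width` bp either side of it, and footprint depth is the central
#' mean minus the flanking accessibility (negative for a true footprint).
#'
#' @param values numeric signal vector (e.g. an aggregate profile).
#' @param width motif width; with a profile of length `width + 2 *
#'   halfwidth` the centre is inferred as `halfwidth + floor(width / 2)`.
#' @param centre optional explicit 0-based centre position within
#'   `values`, overriding the inference.
#' @param central_halfwidth,flank_width region geometry (defaults 12 / 60
#'   bp).
#' @return List with `flanking_accessibility` and `footprint_depth`.
#' @export
footprint_metrics <- function(values, width = NULL, centre = NULL,
                              central_halfwidth = 12L, flank_width = 60L) {
  if (is.null(centre)) {
    if (is.null(width)) stop("provide width or centre")
    halfwidth <- (length(values) - width) / 2
    if (halfwidth != round(halfwidth) || halfwidth < 0) {
      stop("profile length does not match width plus symmetric flanks")
    }
    centre <- as.integer(halfwidth + width %/% 2)
  }
  lo <- centre - central_halfwidth - flank_width
  hi <- centre + central_halfwidth + flank_width
  if (lo < 0 || hi > length(values)) {
    stop("window too short for central region plus flanks")
  }
  idx <- function(a, b) values[(a + 1L):b]  # 0-based half-open [a, b)
  central <- idx(centre - central_halfwidth, centre + central_halfwidth)
  flanks <- c(idx(lo, centre - central_halfwidth),
              idx(centre + central_halfwidth, hi))
  flanking <- mean(flanks)
  list(flanking_accessibility = flanking,
       footprint_depth = mean(central) - flanking)
}

#' Change in footprint metrics between two days
#'
#' @param metrics_a,metrics_b lists from [footprint_metrics()] (days A and
#'   B).
#' @return List with `d_flanking_accessibility` and `d_footprint_depth`
#'   (B minus A).
#' @export
delta_metrics <- function(metrics_a, metrics_b) {
  list(d_flanking_accessibility = metrics_b$flanking_accessibility -
         metrics_a$flanking_accessibility,
       d_footprint_depth = metrics_b$footprint_depth -
         metrics_a$footprint_depth)
}

#' Per-occurrence footprint scores across days
#'
#' The footprint score combines motif match and local accessibility
#' depletion: `score = w_m * norm_llr + w_d * (flanking - central_mean)`,
#' where `norm_llr` is the occurrence's log-likelihood-ratio score min-max
#' scaled to `[0, 1]` within its motif's occurrence set. The score is
#' monotone increasing in depletion at fixed motif match.
#'
#' @param tracks named list of `ef_track`s, one per day (names like
#'   `d0`, `d3`, `d5`).
#' @param occs occurrence data.frame with `chrom`, `start`, `end`,
#'   `strand`, `motif_id`, `llr_score` (genomic coordinates).
#' @param w_m,w_d weights of the match and depletion terms (defaults 0.3 /
#'   0.7).
#' @param central_halfwidth,flank_width footprint geometry.
#' @return data.frame: one row per occurrence with `occurrence_id`,
#'   `motif_id` and one `score_<day>` column per track.
#' @export
occurrence_scores <- function(tracks, occs, w_m = 0.3, w_d = 0.7,
                              central_halfwidth = 12L, flank_width = 60L) {
  if (nrow(occs) == 0) stop("no occurrences")
  norm_llr <- stats::ave(occs$llr_score, occs$motif_id, FUN = function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
  })
  centres <- occs$start + (occs$end - occs$start) %/% 2L
  out <- data.frame(occurrence_id = seq_len(nrow(occs)),
                    motif_id = occs$motif_id, stringsAsFactors = FALSE)
  span <- central_halfwidth + flank_width
  for (day in names(tracks)) {
    tr <- tracks[[day]]
    depl <- vapply(seq_len(nrow(occs)), function(i) {
      v <- track_query(tr, occs$chrom[i], centres[i] - span,
                       centres[i] + span)
      m <- footprint_metrics(v, centre = span,
                             central_halfwidth = central_halfwidth,
                             flank_width = flank_width)
      -m$footprint_depth  # flanking minus central mean
    }, 1.0)
    out[[paste0("score_", day)]] <- w_m * norm_llr + w_d * depl
  }
  out
}

#' Classify motif occurrences as bound or unbound
#'
#' Fits a one-dimensional two-component Gaussian mixture to a motif's
#' occurrence scores; occurrences with posterior probability > 0.5 for the
#' upper component are bound. Degenerate fits (a single mode preferred, or
#' constant scores) yield all-unbound with a warning.
#'
#' @param scores numeric vector of occurrence scores for one motif/day.
#' @param min_n minimum occurrences (default 20).
#' @return Logical vector, `TRUE` for bound.
#' @export
classify_bound <- function(scores, min_n = 20L) {
  if (length(scores) < min_n) {
    stop(sprintf("need >= %d occurrences", min_n))
  }
  if (stats::sd(scores) == 0) {
    warning("constant scores; all occurrences unbound")
    return(rep(FALSE, length(scores)))
  }
  n <- length(scores)
  z0 <- matrix(0, n, 2)
  z0[cbind(seq_len(n),
           ifelse(stats::kmeans(scores, 2, nstart = 3)$cluster == 1, 1, 2))] <- 1
  fit <- suppressWarnings(
    tryCatch(mclust::meV(data = scores, z = z0),
             error = function(e) NULL))
  sd1 <- stats::sd(scores) * sqrt((n - 1) / n)
  loglik1 <- sum(stats::dnorm(scores, mean(scores), sd1, log = TRUE))
  bic1 <- -2 * loglik1 + 2 * log(n)
  if (is.null(fit) || is.na(fit$loglik)) {
    warning("degenerate mixture fit; all occurrences unbound")
    return(rep(FALSE, length(scores)))
  }
  bic2 <- -2 * fit$loglik + 5 * log(n)
  if (bic2 >= bic1) {
    warning("single-mode score distribution; all occurrences unbound")
    return(rep(FALSE, length(scores)))
  }
  upper <- which.max(fit$parameters$mean)
  fit$z[, upper] > 0.5
}

#' Differential binding between two days
#'
#' Per motif, the change in mean occurrence footprint score from day A to
#' day B; standardized against the distribution of changes across all
#' motifs (z mean 0, sd 1 by construction) with two-sided normal-tail
#' p-values. Deltas are antisymmetric in (A, B).
#'
#' @param scores data.frame from [occurrence_scores()].
#' @param dayA,dayB day labels matching the `score_<day>` columns.
#' @param min_occ motifs with fewer occurrences are flagged low
#'   confidence (default 10).
#' @return data.frame per motif: `motif_id`, `n_occurrences`, `delta`,
#'   `z`, `p`, `low_confidence`.
#' @export
differential_binding <- function(scores, dayA, dayB, min_occ = 10L) {
  ca <- paste0("score_", dayA)
  cb <- paste0("score_", dayB)
  if (!all(c(ca, cb) %in% colnames(scores))) {
    stop("scores must contain both days")
  }
  sp <- split(scores, scores$motif_id)
  out <- data.frame(
    motif_id = names(sp),
    n_occurrences = vapply(sp, nrow, 1L),
    delta = vapply(sp, function(d) mean(d[[cb]]) - mean(d[[ca]]), 1.0),
    stringsAsFactors = FALSE)
  sd_d <- stats::sd(out$delta)
  out$z <- if (is.na(sd_d) || sd_d == 0) 0 else
    (out$delta - mean(out$delta)) / sd_d
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$low_confidence <- out$n_occurrences < min_occ
  rownames(out) <- NULL
  out
}

#' Correlate occurrence footprint-score trajectories with TF expression
#'
#' Pearson correlation per occurrence between its footprint-score
#' trajectory and the corresponding TF's expression over the shared day
#' grid; the median per motif is reported. Constant trajectories are
#' dropped.
#'
#' @param scores data.frame from [occurrence_scores()] with `score_<day>`
#'   columns.
#' @param motif_tf named character vector, motif_id -> TF name.
#' @param expr_days TFs-by-days expression matrix on the shared grid.
#' @param subset optional logical/integer vector selecting occurrences
#'   (e.g. those in EF-up TAD peaks).
#' @return data.frame per motif: `motif_id`, `tf`, `n`, `median_r`.
#' @export
footprint_expression_correlation <- function(scores, motif_tf, expr_days,
                                             subset = NULL) {
  if (!is.null(subset)) scores <- scores[subset, , drop = FALSE]
  day_cols <- grep("^score_d", colnames(scores), value = TRUE)
  days <- sub("^score_", "", day_cols)
  if (!all(days %in% colnames(expr_days))) {
    stop("expression matrix missing day(s): ",
         paste(setdiff(days, colnames(expr_days)), collapse = ", "))
  }
  sp <- split(scores, scores$motif_id)
  out <- lapply(names(sp), function(m) {
    tf <- motif_tf[[m]]
    if (is.null(tf) || !(tf %in% rownames(expr_days))) return(NULL)
    e <- expr_days[tf, days]
    if (stats::sd(e) == 0) return(NULL)
    smat <- as.matrix(sp[[m]][, day_cols, drop = FALSE])
    ok <- apply(smat, 1, stats::sd) > 0
    rs <- if (any(ok)) as.numeric(stats::cor(e, t(smat[ok, , drop = FALSE])))
          else numeric(0)
    data.frame(motif_id = m, tf = tf, n = sum(ok),
               median_r = if (length(rs)) stats::median(rs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(out) <- NULL
  out
}
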