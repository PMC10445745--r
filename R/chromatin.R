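#' Merge per-day peak sets into a consensus peak universe
#'
#' Overlapping or book-ended intervals are merged (bedtools-merge
#' semantics), then any interval overlapping a blacklist region is removed.
#' Consensus peaks get stable integer IDs in (chrom, start) order.
#'
#' @param peak_sets list of BED-like data.frames (`chrom`, `start`, `end`).
#' @param blacklist optional BED-like data.frame of regions to exclude.
#' @return BED-like data.frame of consensus peaks with `peak_id`.
#' @export
merge_consensus <- function(peak_sets, blacklist = NULL) {
  all <- do.call(rbind, lapply(peak_sets, function(df) {
    df[, c("chrom", "start", "end")]
  }))
  gr <- GenomicRanges::reduce(as_granges0(all))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hits <- GenomicRanges::findOverlaps(gr, as_granges0(blacklist))
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop) > 0) gr <- gr[-drop]
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(peak_id = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
}

#' Normalize peak accessibility with width/GC correction
#'
#' Per-day library-size scaling to a fixed total (so rescaling any single
#' day's raw signal leaves its normalized values unchanged), log2(x+1)
#' transform, then
#' subtraction of a covariate trend estimated as the median signal in 2-D
#' (GC-decile x width-decile) bins, centred so that a single-bin (no
#' covariate variation) input reduces to library-size scaling plus log.
#' Each day's mean is preserved.
#'
#' @param raw peaks x days matrix of raw accessibility signal.
#' @param gc per-peak GC fraction in `[0, 1]`.
#' @param width per-peak width in bp.
#' @param target fixed column total after scaling (default: 100 x the
#'   number of peaks, i.e. an average scaled signal of 100 per peak).
#' @return Matrix of normalized log2 accessibility, same dimensions as
#'   `raw`.
#' @export
normalize_accessibility <- function(raw, gc, width,
                                    target = 100 * nrow(raw)) {
  raw <- as.matrix(raw)
  if (length(gc) != nrow(raw) || length(width) != nrow(raw)) {
    stop("gc and width must have one value per peak")
  }
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]")
  if (any(width < 1)) stop("width must be >= 1")
  totals <- colSums(raw)
  scaled <- sweep(raw, 2, target / totals, "*")
  lg <- log2(scaled + 1)
  gc_bin <- decile_bin(gc)
  w_bin <- decile_bin(width)
  bin <- interaction(gc_bin, w_bin, drop = TRUE)
  out <- lg
  min_count <- min(table(bin))
  for (j in seq_len(ncol(lg))) {
    x <- lg[, j]
    if (nlevels(bin) > 1 && min_count >= 2) {
      med <- tapply(x, bin, stats::median)
      dev <- med[as.character(bin)] - stats::median(x)
    } else if (nlevels(bin) > 1) {
      # sparse 2-D bins: fall back to marginal decile corrections
      message("normalize_accessibility: sparse 2-D bins, ",
              "using marginal decile correction")
      dg <- tapply(x, gc_bin, stats::median)[as.character(gc_bin)]
      dw <- tapply(x, w_bin, stats::median)[as.character(w_bin)]
      dev <- (dg - stats::median(x)) + (dw - stats::median(x))
    } else {
      dev <- 0
    }
    y <- x - dev
    out[, j] <- y - mean(y) + mean(x)
  }
  out
}

decile_bin <- function(x) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(br) < 2) return(factor(rep(1, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Annotate peaks by genomic context
#'
#' Categories partition the peak universe with fixed precedence:
#' promoter (overlap with TSS +/- `promoter_window`) > exonic > intronic >
#' intergenic.
#'
#' @param peaks BED-like data.frame with `peak_id`, `chrom`, `start`, `end`.
#' @param genes gene-model data.frame with `gene`, `chrom`, `start`, `end`,
#'   `strand` and comma-separated `exon_starts` / `exon_ends` (absolute,
#'   0-based half-open).
#' @param promoter_window bp either side of the TSS (default 1000).
#' @return Character vector of annotations, one per peak.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = 1000L) {
  pk <- as_granges0(peaks, strand = "*")
  tss <- gene_tss(genes)
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(tss - promoter_window, 0L) + 1L,
                     tss + promoter_window))
  exons <- gene_exons(genes)
  body <- as_granges0(genes, strand = "*")
  ann <- rep("intergenic", nrow(peaks))
  in_body <- overlaps_any(pk, body)
  ann[in_body] <- "intronic"
  ann[overlaps_any(pk, exons)] <- "exonic"
  ann[overlaps_any(pk, prom)] <- "promoter"
  ann
}

overlaps_any <- function(query, subject) {
  IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

# 0-based TSS position per gene: start for +, end - 1 for -.
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

gene_exons <- function(genes) {
  starts <- lapply(strsplit(as.character(genes$exon_starts), ","),
                   as.integer)
  ends <- lapply(strsplit(as.character(genes$exon_ends), ","), as.integer)
  chrom <- rep(genes$chrom, lengths(starts))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(unlist(starts) + 1L,
                                          unlist(ends)))
}

#' Classify dynamic accessibility peaks between two days
#'
#' A peak is `opening` when its normalized log2 signal increases by
#' strictly more than `lfc_thresh` from day A to day B, `closing` when it
#' decreases by strictly more, and `static` otherwise.
#'
#' @param norm peaks x days matrix of normalized log2 accessibility with
#'   day-named columns (e.g. `d3`, `d5`).
#' @param dayA,dayB column names of the day pair (defaults `d3`, `d5`).
#' @param lfc_thresh log2-fold-change gate (default 1.5).
#' @return data.frame with `peak_id` (rownames of `norm`, as integer when
#'   possible), `delta` and `dynamic_class`.
#' @export
dynamic_peaks <- function(norm, dayA = "d3", dayB = "d5", lfc_thresh = 1.5) {
  if (!all(c(dayA, dayB) %in% colnames(norm))) {
    stop("both days must be present in the normalized matrix")
  }
  delta <- norm[, dayB] - norm[, dayA]
  cls <- ifelse(delta > lfc_thresh, "opening",
                ifelse(delta < -lfc_thresh, "closing", "static"))
  ids <- rownames(norm)
  ids_int <- suppressWarnings(as.integer(ids))
  data.frame(peak_id = if (!any(is.na(ids_int))) ids_int else ids,
             delta = unname(delta), dynamic_class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Assign peaks and genes to TADs and inter-TAD gaps
#'
#' Gap regions are synthesized between genomically adjacent TADs so that
#' TADs and gaps tile each chromosome's TAD-spanned extent. Peaks are
#' assigned by midpoint, genes by TSS. Region classes come from the gene
#' sets: a region containing at least one EF-up gene is flagged `ef_up`
#' (dually labelled when it also contains EF-down genes), housekeeping
#' regions contain stably expressed genes and no EF genes.
#'
#' @param tads BED-like data.frame of TAD intervals (non-overlapping per
#'   chromosome).
#' @param peaks BED-like data.frame with `peak_id`.
#' @param genes gene-model data.frame (see [annotate_peaks()]).
#' @param gene_sets list with character vectors `ef_up`, `ef_down`,
#'   `housekeeping`.
#' @return List with `regions` (region table with `region_id`, `kind`,
#'   class flags and `class` summary), `peak_region` (peak_id ->
#'   region_id, NA outside the TAD-spanned extent) and `gene_region`.
#' @export
assign_tads <- function(tads, peaks, genes, gene_sets) {
  regions <- build_regions(tads)
  pk_mid <- (peaks$start + peaks$end) %/% 2L
  peak_region <- locate_in_regions(peaks$chrom, pk_mid, regions)
  gene_region <- locate_in_regions(genes$chrom, gene_tss(genes), regions)
  regions$n_genes <- 0L
  regions$is_ef_up <- regions$is_ef_down <- regions$is_housekeeping <- FALSE
  for (i in seq_len(nrow(regions))) {
    g <- genes$gene[!is.na(gene_region) & gene_region == regions$region_id[i]]
    regions$n_genes[i] <- length(g)
    regions$is_ef_up[i] <- any(g %in% gene_sets$ef_up)
    regions$is_ef_down[i] <- any(g %in% gene_sets$ef_down)
    regions$is_housekeeping[i] <- any(g %in% gene_sets$housekeeping)
  }
  cls <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    tags <- c(if (regions$is_ef_up[i]) "ef_up",
              if (regions$is_ef_down[i]) "ef_down")
    if (length(tags) == 0 && regions$is_housekeeping[i]) tags <- "housekeeping"
    if (length(tags) == 0) tags <- "other"
    cls[i] <- paste(tags, collapse = "|")
  }
  regions$class <- cls
  if (any(regions$is_ef_up & regions$is_ef_down)) {
    message(sum(regions$is_ef_up & regions$is_ef_down),
            " region(s) contain both EF-up and EF-down genes; dually labelled")
  }
  list(regions = regions,
       peak_region = stats::setNames(peak_region, peaks$peak_id),
       gene_region = stats::setNames(gene_region, genes$gene))
}

build_regions <- function(tads) {
  out <- list()
  for (chrom in unique(tads$chrom)) {
    t <- tads[tads$chrom == chrom, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)])) {
      stop(sprintf("overlapping TADs on %s", chrom))
    }
    rows <- data.frame(chrom = chrom, start = t$start, end = t$end,
                       kind = "tad", stringsAsFactors = FALSE)
    if (nrow(t) > 1) {
      gs <- t$end[-nrow(t)]
      ge <- t$start[-1]
      keep <- ge > gs
      if (any(keep)) {
        rows <- rbind(rows, data.frame(chrom = chrom, start = gs[keep],
                                       end = ge[keep], kind = "gap",
                                       stringsAsFactors = FALSE))
      }
    }
    out[[chrom]] <- rows
  }
  regions <- do.call(rbind, out)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  data.frame(region_id = paste0(ifelse(regions$kind == "tad", "tad_", "gap_"),
                                seq_len(nrow(regions))),
             regions, stringsAsFactors = FALSE)
}

# Assign 0-based positions to regions (half-open containment).
locate_in_regions <- function(chrom, pos, regions) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- chrom == regions$chrom[i] & pos >= regions$start[i] &
      pos < regions$end[i]
    out[hit] <- regions$region_id[i]
  }
  out
}

#' Region-gene associations by a basal-plus-extension rule
#'
#' Each gene gets a basal regulatory domain (`basal_up` bp upstream,
#' `basal_down` bp downstream of its TSS, strand-aware), extended in both
#' directions up to the nearest neighbouring basal domain or at most
#' `max_extension` bp from the TSS. A peak links to every gene whose
#' regulatory domain it overlaps.
#'
#' @param peaks BED-like data.frame with `peak_id`.
#' @param genes gene-model data.frame with strand.
#' @param basal_up,basal_down basal domain extent (defaults 5000 / 1000 bp).
#' @param max_extension cap on the extension (default 1e6 bp).
#' @return data.frame with columns `peak_id`, `gene`.
#' @export
region_gene_associations <- function(peaks, genes, basal_up = 5000L,
                                     basal_down = 1000L,
                                     max_extension = 1000000L) {
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, tss - basal_up, tss - basal_down + 1L)
  basal_end <- ifelse(plus, tss + basal_down, tss + basal_up + 1L)
  basal_start <- pmax(basal_start, 0L)
  dom_start <- dom_end <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    others <- setdiff(same, i)
    left_ends <- basal_end[others][basal_end[others] <= basal_start[i]]
    left_bound <- if (length(left_ends) > 0) max(left_ends) else 0L
    right_starts <- basal_start[others][basal_start[others] >= basal_end[i]]
    right_bound <- if (length(right_starts) > 0) min(right_starts) else Inf
    dom_start[i] <- max(tss[i] - max_extension, left_bound)
    dom_start[i] <- min(dom_start[i], basal_start[i])
    dom_end[i] <- min(tss[i] + max_extension, right_bound)
    dom_end[i] <- max(dom_end[i], basal_end[i])
  }
  dom <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(dom_start, 0L) + 1L,
                                                 dom_end))
  pk <- as_granges0(peaks, strand = "*")
  hits <- GenomicRanges::findOverlaps(pk, dom, ignore.strand = TRUE)
  data.frame(peak_id = peaks$peak_id[S4Vectors::queryHits(hits)],
             gene = genes$gene[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Location and variability statistics for two peak groups
#'
#' Compares per-peak time-mean signal (location) and per-peak trajectory
#' standard deviation across days (variability) between two groups with
#' two-sided Mann-Whitney U tests. The exact null distribution is used
#' when both groups have at most `exact_max` observations and there are no
#' ties; otherwise the normal approximation with tie correction.
#'
#' @param groupA,groupB peaks x days matrices of normalized signal.
#' @param exact_max exact-test size cutoff per group (default 8).
#' @return List with group medians of time-mean signal, median trajectory
#'   sd, and `p_location`, `p_variability`.
#' @export
promoter_stats <- function(groupA, groupB, exact_max = 8L) {
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  if (nrow(groupA) < 2 || nrow(groupB) < 2) {
    stop("each group needs >= 2 peaks")
  }
  ma <- rowMeans(groupA)
  mb <- rowMeans(groupB)
  va <- apply(groupA, 1, stats::sd)
  vb <- apply(groupB, 1, stats::sd)
  list(median_mean_a = stats::median(ma), median_mean_b = stats::median(mb),
       median_sd_a = stats::median(va), median_sd_b = stats::median(vb),
       p_location = mw_test(ma, mb, exact_max),
       p_variability = mw_test(va, vb, exact_max))
}

mw_test <- function(x, y, exact_max = 8L) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}
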