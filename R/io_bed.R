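#' Read a BED-like interval file
#'
#' Accepts BED3/BED6 and 10-column narrowPeak. Coordinates are 0-based
#' half-open, the convention used throughout the package: the length of an
#' interval is always `end - start`. Input need not be sorted; output is
#' sorted by (chrom, start, end) and assigned stable integer `peak_id`s in
#' sorted order. Exact duplicate intervals are collapsed with a warning.
#'
#' @param path path to a tab-separated BED/narrowPeak file (no header).
#' @return A data.frame with columns `peak_id`, `chrom`, `start`, `end` and,
#'   when present in the input, `name`, `score`, `strand`, `signal`,
#'   `pvalue`, `qvalue`, `summit` (summit offset relative to `start`).
#' @export
read_bed_like <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  bed_like(df)
}

bed_like <- function(df) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit")
  if (ncol(df) < 3) stop("BED input needs at least 3 columns")
  n <- min(ncol(df), length(cols))
  df <- df[, seq_len(n), drop = FALSE]
  colnames(df) <- cols[seq_len(n)]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-integer start/end coordinate in BED input")
  }
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop(sprintf("interval with start >= end at input row %d (%s:%d-%d)",
                 bad, df$chrom[bad], df$start[bad], df$end[bad]))
  }
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end")])
  if (any(dup)) {
    warning(sprintf("%d duplicate interval(s) collapsed", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  data.frame(peak_id = seq_len(nrow(df)), df, stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional further
#'   BED columns (written in BED column order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand",
                      "signal", "pvalue", "qvalue", "summit"),
                    colnames(df))
  # BED columns are positional: stop at the first absent one
  keep <- character(0)
  for (cl in c("chrom", "start", "end", "name", "score", "strand",
               "signal", "pvalue", "qvalue", "summit")) {
    if (cl %in% cols) keep <- c(keep, cl) else break
  }
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interval length under the half-open convention
#'
#' @param start,end 0-based half-open interval bounds (vectorized).
#' @return `end - start`.
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  end - start
}

# Convert 0-based half-open intervals to a GRanges (1-based closed).
as_granges0 <- function(df, strand = NULL) {
  s <- if (!is.null(strand)) strand
       else if ("strand" %in% colnames(df)) ifelse(df$strand %in% c("+", "-"),
                                                   df$strand, "*")
       else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = s)
}
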