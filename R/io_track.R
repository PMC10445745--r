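#' Per-basepair signal track
#'
#' In-memory representation of a bias-corrected accessibility track: one
#' numeric vector per chromosome covering positions `[0, length)` (0-based).
#' Positions beyond the stored vectors read as 0.
#'
#' @param values named list of numeric vectors, one per chromosome; element
#'   `i` of a vector is the signal at 0-based position `i - 1`.
#' @return An object of class `ef_track`.
#' @export
ef_track <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("track chromosomes must be named")
  }
  if (any(vapply(values, function(v) any(is.na(v)), TRUE))) {
    stop("track values must not contain NA")
  }
  structure(list(values = lapply(values, as.numeric)), class = "ef_track")
}

#' @export
print.ef_track <- function(x, ...) {
  cat(sprintf("ef_track: %d chromosome(s), %s bp total\n",
              length(x$values),
              format(sum(vapply(x$values, length, 1L)), big.mark = ",")))
  invisible(x)
}

#' Query per-bp signal over a window
#'
#' @param track an `ef_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return Numeric vector of length `end - start`; positions absent from the
#'   track (unknown chromosome or beyond its stored extent) read as 0.
#' @export
track_query <- function(track, chrom, start, end) {
  if (end < start) stop("end must be >= start")
  n <- end - start
  out <- numeric(n)
  v <- track$values[[chrom]]
  if (is.null(v) || n == 0) return(out)
  # overlap of [start, end) with [0, length(v))
  lo <- max(start, 0L)
  hi <- min(end, length(v))
  if (hi > lo) {
    out[(lo - start + 1L):(hi - start)] <- v[(lo + 1L):hi]
  }
  out
}

#' Read a bedGraph file into a track
#'
#' Intervals must be non-overlapping within each chromosome; gaps read
#' as 0.
#'
#' @param path path to a 4-column bedGraph file (chrom, start, end, value).
#' @return An `ef_track`.
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns")
  colnames(df)[1:4] <- c("chrom", "start", "end", "value")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$value <- as.numeric(df$value)
  if (any(df$start >= df$end)) stop("bedGraph interval with start >= end")
  values <- list()
  for (chrom in unique(df$chrom)) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop(sprintf("overlapping bedGraph intervals on %s", chrom))
    }
    v <- numeric(max(sub$end))
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
    values[[chrom]] <- v
  }
  ef_track(values)
}

#' Write a track as bedGraph
#'
#' Runs of equal value are emitted as single intervals; zero runs are
#' omitted (they are implicit on read).
#'
#' @param track an `ef_track`.
#' @param path output path.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- round(track$values[[chrom]], digits)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         formatC(r$values[keep], format = "f",
                                 digits = digits, drop0trailing = TRUE)),
                 con)
    }
  }
  invisible(path)
}

#' Write result tables as TSV
#'
#' Shared writer for the pipeline's tabular outputs.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
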