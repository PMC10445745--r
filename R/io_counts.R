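#' Parse sample identifiers into sample metadata
#'
#' Sample identifiers follow the pattern `d<day>[p|n]_r<replicate>`, e.g.
#' `d0_r1`, `d4p_r2` (day-4 GFP-positive), `d5n_r3` (day-5 GFP-negative).
#' The GFP suffix is only allowed for days 4 and 5, matching the sorting
#' design of the time course.
#'
#' @param sample_ids character vector of sample identifiers.
#' @return A data.frame with columns `sample_id`, `day`, `replicate`, `gfp`
#'   (`positive`, `negative` or `unsorted`).
#' @export
parse_sample_meta <- function(sample_ids) {
  m <- regmatches(sample_ids,
                  regexec("^d([0-9]+)([pn]?)_r([0-9]+)$", sample_ids))
  bad <- sample_ids[vapply(m, length, 1L) != 4L]
  if (length(bad) > 0) {
    stop("malformed sample identifier(s): ", paste(bad, collapse = ", "))
  }
  day <- vapply(m, function(x) as.integer(x[2]), 1L)
  gfp_code <- vapply(m, function(x) x[3], "")
  rep <- vapply(m, function(x) as.integer(x[4]), 1L)
  gfp <- c(p = "positive", n = "negative")[gfp_code]
  gfp[is.na(gfp)] <- "unsorted"
  if (any(day < 0 | day > 5)) stop("day must be in 0..5")
  if (any(rep < 1)) stop("replicate must be >= 1")
  if (any(gfp != "unsorted" & day < 4)) {
    stop("GFP-sorted samples are only allowed for days >= 4")
  }
  meta <- data.frame(sample_id = sample_ids, day = day, replicate = rep,
                     gfp = unname(gfp), stringsAsFactors = FALSE)
  if (anyDuplicated(meta[, c("day", "replicate", "gfp")])) {
    stop("duplicate (day, replicate, gfp) combination in sample metadata")
  }
  meta
}

#' Build a count matrix object
#'
#' @param counts integer matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs parseable by [parse_sample_meta()]).
#' @return An object of class `ef_counts`: list with elements `counts` and
#'   `meta`.
#' @export
ef_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, meta = parse_sample_meta(colnames(counts))),
            class = "ef_counts")
}

#' @export
print.ef_counts <- function(x, ...) {
  cat(sprintf("ef_counts: %d genes x %d samples (days %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$meta$day)), collapse = ",")))
  invisible(x)
}

#' Read a gene-level count matrix from TSV
#'
#' First column holds gene IDs; remaining column names are sample identifiers
#' encoding day/replicate/GFP status (see [parse_sample_meta()]).
#'
#' @param path path to a tab-separated file.
#' @return An `ef_counts` object.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    col <- suppressWarnings(as.numeric(mat[, j]))
    if (any(is.na(col))) {
      stop(sprintf("non-numeric count in column '%s'", colnames(mat)[j]))
    }
    if (any(col < 0) || any(col != round(col))) {
      stop(sprintf("negative or non-integer count in column '%s'",
                   colnames(mat)[j]))
    }
  }
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  ef_counts(mat)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` reproduces
#' `x`.
#'
#' @param x an `ef_counts` object or integer matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  mat <- if (inherits(x, "ef_counts")) x$counts else x
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
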