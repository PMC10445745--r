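#' Read JASPAR-style position frequency matrices
#'
#' Parses the JASPAR text format: a header line `>MOTIF_ID TF_NAME` followed
#' by four rows of counts for A, C, G, T, with or without `A [ ... ]`
#' decoration. Multiple motifs may map to the same TF name; they are retained
#' individually and grouped under that TF downstream (motif presence is
#' collapsed per TF).
#'
#' @param path path to a PFM text file.
#' @return An object of class `ef_motifs`: a list of motifs, each a list with
#'   `id`, `tf` and `pfm` (4 x width numeric matrix with rownames A,C,G,T).
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif header ('>') found")
  motifs <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    tf <- if (length(parts) >= 2) parts[2] else parts[1]
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      stop(sprintf("motif '%s': expected 4 count rows, got %d",
                   id, length(body)))
    }
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[|\\]\\s*$", "", trimws(ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(vals))) stop(sprintf("motif '%s': non-numeric count", id))
      vals
    })
    w <- unique(vapply(rows, length, 1L))
    if (length(w) != 1) {
      stop(sprintf("motif '%s': unequal row lengths", id))
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0)) stop(sprintf("motif '%s': negative count", id))
    if (any(colSums(pfm) == 0)) {
      stop(sprintf("motif '%s': column with zero total count", id))
    }
    motifs[[i]] <- list(id = id, tf = tf, pfm = pfm)
  }
  ids <- vapply(motifs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicated motif IDs")
  names(motifs) <- ids
  structure(motifs, class = "ef_motifs")
}

#' Write motifs in JASPAR text format
#'
#' @param motifs an `ef_motifs` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$tf), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$pfm[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @export
print.ef_motifs <- function(x, ...) {
  cat(sprintf("ef_motifs: %d motif(s), %d TF(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "tf")))))
  invisible(x)
}

#' Consensus sequence of a position frequency matrix
#'
#' @param pfm 4 x width count matrix with rownames A,C,G,T.
#' @return Character scalar, the per-column argmax base (ties broken by
#'   A<C<G<T order).
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

#' TF names of a motif set
#' @param motifs an `ef_motifs` object.
#' @return Named character vector mapping motif id to TF name.
#' @export
motif_tfs <- function(motifs) {
  vapply(motifs, `[[`, "", "tf")
}
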