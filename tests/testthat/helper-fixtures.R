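# Small in-code fixtures shared across test files.

toy_counts_file <- function(mat) {
  path <- tempfile(fileext = ".tsv")
  write_counts(mat, path)
  path
}

toy_gene <- function(gene = "g1", chrom = "chr1", start = 5000L,
                     end = 5900L, strand = "+") {
  data.frame(gene = gene, chrom = chrom, start = start, end = end,
             strand = strand,
             exon_starts = paste(start, end - 150L, sep = ","),
             exon_ends = paste(start + 150L, end, sep = ","),
             stringsAsFactors = FALSE)
}

toy_peaks <- function(starts, ends, chrom = "chr1") {
  data.frame(peak_id = seq_along(starts), chrom = chrom,
             start = as.integer(starts), end = as.integer(ends),
             stringsAsFactors = FALSE)
}

# A single-motif set with the given consensus, strongly peaked PFM.
toy_motifs <- function(consensus = "ACGTACGT", tf = "tfX",
                       id = paste0("M_", tf)) {
  pfm <- matrix(1, 4, nchar(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], rownames(pfm))
  pfm[cbind(idx, seq_len(ncol(pfm)))] <- 18
  structure(list(list(id = id, tf = tf, pfm = pfm)) |>
              stats::setNames(id), class = "ef_motifs")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Deterministic flat track over one chromosome.
flat_track <- function(value, len = 1000L, chrom = "chr1") {
  ef_track(stats::setNames(list(rep(value, len)), chrom))
}
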