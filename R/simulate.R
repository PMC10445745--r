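#' Simulate a toy genome with TADs, genes and accessibility peaks
#'
#' Builds a small multi-chromosome genome in which non-overlapping TADs
#' are separated by inter-TAD gaps. Each TAD carries a block of genes (two
#' exons flanking one intron) and a block of non-overlapping peaks; the
#' first peak of every TAD sits on the first gene's TSS (a promoter peak).
#' The first gap of each chromosome carries one gene and a handful of
#' peaks, mirroring genes that fall between TADs. Peak sequences are
#' i.i.d. background nucleotides (motifs are embedded later, see
#' [simulate_truth()]).
#'
#' @param n_tads total number of TADs (split across `n_chrom`
#'   chromosomes).
#' @param genes_per_tad,peaks_per_tad elements per TAD.
#' @param seed RNG seed; identical seeds give identical output.
#' @param n_chrom number of chromosomes (default 2).
#' @param tad_width,gap_width,peak_width geometry in bp.
#' @param n_gap_peaks peaks placed in each populated gap (default 6).
#' @return List with `tads`, `genes`, `peaks` (BED-like data.frames),
#'   `sequences` (named character, background only), `chrom_lengths`,
#'   and `gap_genes` (genes living in inter-TAD gaps).
#' @export
simulate_genome <- function(n_tads = 12L, genes_per_tad = 4L,
                            peaks_per_tad = 24L, seed = 1L,
                            n_chrom = 2L, tad_width = 15000L,
                            gap_width = 6000L, peak_width = 400L,
                            n_gap_peaks = 6L) {
  if (n_tads < 1 || genes_per_tad < 1 || peaks_per_tad < 1) {
    stop("counts must be >= 1")
  }
  gene_len <- 900L
  gene_zone <- 200L + genes_per_tad * 950L
  need <- gene_zone + 100L + peaks_per_tad * (peak_width + 20L)
  if (need > tad_width) {
    stop(sprintf("tad_width %d too small for requested elements (need %d)",
                 tad_width, need))
  }
  set.seed(seed)
  chroms <- paste0("chr", LETTERS[seq_len(n_chrom)])
  per_chrom <- rep(n_tads %/% n_chrom, n_chrom)
  extra <- n_tads %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  tads <- genes <- peaks <- list()
  gap_genes <- character(0)
  chrom_lengths <- integer(0)
  tad_i <- 0L
  for (ci in seq_len(n_chrom)) {
    chrom <- chroms[ci]
    nt <- per_chrom[ci]
    if (nt == 0) next
    pos <- 1000L
    for (t in seq_len(nt)) {
      tad_i <- tad_i + 1L
      ts <- pos
      te <- ts + tad_width
      tads[[tad_i]] <- data.frame(chrom = chrom, start = ts, end = te,
                                  name = paste0("tad", tad_i),
                                  stringsAsFactors = FALSE)
      for (g in seq_len(genes_per_tad)) {
        gs <- ts + 200L + (g - 1L) * 950L
        strand <- if (g %% 2 == 1) "+" else "-"
        genes[[length(genes) + 1L]] <- gene_row(
          paste0("t", tad_i, "g", g), chrom, gs, gs + gene_len, strand)
      }
      pk0 <- ts + gene_zone + 100L
      spacing <- (tad_width - gene_zone - 100L - peak_width) %/%
        max(peaks_per_tad - 1L, 1L)
      for (k in seq_len(peaks_per_tad)) {
        if (k == 1) {
          # promoter peak over the first gene's TSS
          g1 <- ts + 200L
          ps <- g1 - peak_width %/% 2L
        } else {
          ps <- pk0 + (k - 1L) * spacing
        }
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom, start = ps, end = ps + peak_width,
          stringsAsFactors = FALSE)
      }
      pos <- te
      if (t < nt) {
        # populate the first gap of each chromosome
        if (t == 1 && gap_width >= 1400L + n_gap_peaks * 750L) {
          gname <- paste0("gap", chrom, "_gene")
          gs <- pos + 200L
          genes[[length(genes) + 1L]] <- gene_row(gname, chrom, gs,
                                                  gs + gene_len, "+")
          gap_genes <- c(gap_genes, gname)
          for (k in seq_len(n_gap_peaks)) {
            ps <- pos + 1400L + (k - 1L) * 750L
            peaks[[length(peaks) + 1L]] <- data.frame(
              chrom = chrom, start = ps, end = ps + peak_width,
              stringsAsFactors = FALSE)
          }
        }
        pos <- pos + gap_width
      }
    }
    chrom_lengths[chrom] <- pos + 1000L
  }
  tads <- do.call(rbind, tads)
  genes <- do.call(rbind, genes)
  peaks <- bed_like(do.call(rbind, peaks))
  sequences <- vapply(seq_len(nrow(peaks)), function(i) {
    paste(sample(BASES, peaks$end[i] - peaks$start[i], replace = TRUE),
          collapse = "")
  }, "")
  names(sequences) <- peaks$peak_id
  list(tads = tads, genes = genes, peaks = peaks, sequences = sequences,
       chrom_lengths = chrom_lengths, gap_genes = gap_genes,
       peak_width = peak_width)
}

gene_row <- function(name, chrom, start, end, strand) {
  data.frame(gene = name, chrom = chrom, start = start, end = end,
             strand = strand,
             exon_starts = paste(start, end - 150L, sep = ","),
             exon_ends = paste(start + 150L, end, sep = ","),
             stringsAsFactors = FALSE)
}

# Binding ramps over the ATAC day grid (d0, d1, d2, d3, d5).
BOUND_RAMPS <- list(
  none = c(0, 0, 0, 0, 0),
  act = c(0, 0, 0, 0.5, 1),
  cre = c(0, 0, 0, 0.3, 1),
  rep = c(1, 0.8, 0.5, 0.2, 0)
)
OPEN_RAMP <- c(d0 = 0, d1 = 0.03, d2 = 0.08, d3 = 0.15, d5 = 1)
ATAC_DAYS <- c("d0", "d1", "d2", "d3", "d5")

#' Plant ground truth: TF roles, gene programmes, peak dynamics, motifs
#'
#' Assigns each TAD a class (cycling EF-up, EF-down, housekeeping,
#' housekeeping), gives its genes the matching expression programme
#' (up-after-day-3, gradual-down with one transient gene per EF-down TAD,
#' or stable), designates activator / repressor / inert TFs among the
#' genes, samples each peak's dynamic class, and embeds motif consensus
#' sequences into peak sequences with class-dependent rates: activator
#' motifs preferentially in opening peaks, repressor motifs in closing
#' peaks (and at a lower rate in opening peaks, emulating silenced
#' elements). Each gap gene gets one designated candidate CRE peak
#' carrying all activator motifs with strong planted binding.
#'
#' Activator occurrences in opening peaks are bound with increasing
#' occupancy over days; repressor occurrences in closing peaks with
#' decreasing occupancy. Bound occurrences carry a planted central
#' depletion (recorded as `depth_frac`, the fraction of local amplitude).
#'
#' @param genome output of [simulate_genome()].
#' @param seed RNG seed.
#' @param n_act,n_rep,n_inert TFs per role (defaults 3 / 3 / 10).
#' @param motif_width embedded motif width (default 8).
#' @param embed_rates named list of embedding probabilities per
#'   (role, peak class).
#' @param depth_frac planted footprint depth as a fraction of peak
#'   amplitude (default 0.5; the candidate CRE uses 0.8).
#' @return List of class `ef_truth`: `gene_programme`, `tf_role`,
#'   `tf_genes`, `peak_class`, `motifs` (an `ef_motifs`), `occurrences`
#'   (with `bound_ramp`, `depth_frac`), `sequences` (with embedded
#'   motifs), `cre` (gene -> designated peak_id), `embed_rates`.
#' @export
simulate_truth <- function(genome, seed = 1L, n_act = 3L, n_rep = 3L,
                           n_inert = 10L, motif_width = 8L,
                           embed_rates = list(
                             act = c(opening = 0.95, closing = 0.05,
                                     static = 0.5),
                             rep = c(opening = 0.45, closing = 0.95,
                                     static = 0.35),
                             inert = c(opening = 0.4, closing = 0.4,
                                       static = 0.4)),
                           depth_frac = 0.5) {
  set.seed(seed + 101L)
  tad_classes <- rep_len(c("ef_up", "ef_down", "hk", "hk"),
                         nrow(genome$tads))
  names(tad_classes) <- genome$tads$name
  # gene programmes
  gene_programme <- character(0)
  for (i in seq_len(nrow(genome$tads))) {
    tg <- grep(paste0("^t", i, "g"), genome$genes$gene, value = TRUE)
    prog <- switch(tad_classes[i],
                   ef_up = rep("up_after_d3", length(tg)),
                   ef_down = c(rep("gradual_down", length(tg) - 1),
                               "transient"),
                   hk = rep("stable", length(tg)))
    gene_programme[tg] <- prog
  }
  gene_programme[genome$gap_genes] <- "up_after_d3"
  # TF roles: activators among up genes (one per EF-up TAD), repressors
  # among gradual-down genes, inert among stable genes
  up_tads <- which(tad_classes == "ef_up")
  down_tads <- which(tad_classes == "ef_down")
  act_tfs <- paste0("t", rep_len(up_tads, n_act),
                    "g", 1L + (seq_len(n_act) - 1L) %/% length(up_tads) + 1L)
  rep_tfs <- paste0("t", rep_len(down_tads, n_rep),
                    "g", 1L + (seq_len(n_rep) - 1L) %/% length(down_tads))
  stable_genes <- names(gene_programme)[gene_programme == "stable"]
  if (length(stable_genes) < n_inert) {
    stop("not enough stable genes for the requested inert TFs")
  }
  inert_tfs <- stable_genes[seq_len(n_inert)]
  tf_role <- c(stats::setNames(rep("activator", n_act), act_tfs),
               stats::setNames(rep("repressor", n_rep), rep_tfs),
               stats::setNames(rep("inert", n_inert), inert_tfs))
  if (anyDuplicated(names(tf_role))) stop("TF gene collision; adjust layout")
  tf_genes <- stats::setNames(names(tf_role), names(tf_role))
  # motifs: one consensus per TF (first activator gets a second motif to
  # exercise per-TF collapsing), consensus-dominant counts
  tf_names <- names(tf_role)
  n_motifs <- length(tf_names) + 1L
  consensi <- character(0)
  while (length(consensi) < n_motifs) {
    cand <- paste(sample(BASES, motif_width, replace = TRUE),
                  collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cand)))
    if (!(cand %in% consensi) && !(rc %in% consensi) && cand != rc) {
      consensi <- c(consensi, cand)
    }
  }
  motif_list <- list()
  mi <- 0L
  for (tf in tf_names) {
    nm <- if (tf == tf_names[1]) 2L else 1L
    for (k in seq_len(nm)) {
      mi <- mi + 1L
      id <- paste0("M_", tf, "_", k)
      motif_list[[id]] <- list(id = id, tf = tf,
                               pfm = consensus_pfm(consensi[mi]))
    }
  }
  motifs <- structure(motif_list, class = "ef_motifs")
  # peak dynamic classes
  peaks <- genome$peaks
  peak_tad <- peak_tad_index(genome)
  peak_class <- rep("static", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ti <- peak_tad$tad[i]
    if (!is.na(ti)) {
      if (peak_tad$is_promoter[i]) next  # promoter peaks stay accessible
      cls <- tad_classes[ti]
      p_open <- switch(cls, ef_up = 0.65, ef_down = 0.10, hk = 0)
      p_close <- switch(cls, ef_up = 0.10, ef_down = 0.65, hk = 0)
      u <- stats::runif(1)
      peak_class[i] <- if (u < p_open) "opening"
        else if (u < p_open + p_close) "closing" else "static"
    }
  }
  names(peak_class) <- peaks$peak_id
  # gap target regions: designate the CRE peak (first gap peak) opening,
  # two more opening competitors, rest static
  cre <- character(0)
  for (gg in genome$gap_genes) {
    gp <- gap_peaks_of(genome, gg)
    peak_class[as.character(gp)] <- c("opening", "opening", "opening",
                                      rep("static", length(gp) - 3L))
    cre[gg] <- as.character(gp[1])
  }
  # motif embedding and occurrence truth
  sequences <- genome$sequences
  role_of <- tf_role
  # one embedding slot per TF on a shared non-overlapping grid; TFs whose
  # occurrences can carry footprints get widely separated slots so their
  # central/flank windows do not cover another bound centre
  slots <- 20L + 22L * (0:16)
  if (length(tf_names) > length(slots)) stop("too many TFs for peak width")
  fp_slots <- slots[c(3, 9, 15)]
  rep_slots <- slots[c(1, 6, 12)]
  slot_of <- stats::setNames(rep(NA_integer_, length(tf_names)), tf_names)
  slot_of[act_tfs] <- fp_slots[seq_len(n_act)]
  slot_of[rep_tfs] <- rep_slots[seq_len(n_rep)]
  other <- setdiff(tf_names, c(act_tfs, rep_tfs))
  free <- setdiff(slots, c(fp_slots, rep_slots))
  slot_of[other] <- free[seq_along(other)]
  motif_tf_map <- vapply(motifs, `[[`, "", "tf")
  cons_fwd <- vapply(motifs, function(m) pfm_consensus(m$pfm), "")
  cons_rev <- vapply(cons_fwd, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "")
  ids_of <- lapply(tf_names, function(tf) names(motifs)[motif_tf_map == tf])
  names(ids_of) <- tf_names
  o_pid <- o_tf <- o_mid <- o_strand <- o_ramp <- character(0)
  o_off <- integer(0)
  o_dfrac <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    pid <- as.character(peaks$peak_id[i])
    pcls <- peak_class[pid]
    is_cre <- pid %in% cre
    for (tf in tf_names) {
      role <- role_of[[tf]]
      rate_key <- switch(role, activator = "act", repressor = "rep",
                         inert = "inert")
      p_embed <- embed_rates[[rate_key]][[pcls]]
      if (is_cre && role == "activator") p_embed <- 1
      if (stats::runif(1) >= p_embed) next
      ids <- ids_of[[tf]]
      mid <- if (length(ids) > 1) sample(ids, 1) else ids
      strand <- sample(c("+", "-"), 1)
      emb <- if (strand == "-") cons_rev[[mid]] else cons_fwd[[mid]]
      off <- slot_of[[tf]]
      substr(sequences[pid], off + 1L, off + motif_width) <- emb
      ramp <- "none"
      dfrac <- 0
      if (role == "activator" && pcls == "opening") {
        ramp <- if (is_cre) "cre" else "act"
        dfrac <- if (is_cre) 0.8 else depth_frac
      } else if (role == "repressor" && pcls == "closing") {
        ramp <- "rep"
        dfrac <- depth_frac
      }
      o_pid <- c(o_pid, pid); o_tf <- c(o_tf, tf); o_mid <- c(o_mid, mid)
      o_strand <- c(o_strand, strand); o_ramp <- c(o_ramp, ramp)
      o_off <- c(o_off, off); o_dfrac <- c(o_dfrac, dfrac)
    }
  }
  occurrences <- data.frame(
    peak_id = o_pid, tf = o_tf, motif_id = o_mid, offset = o_off,
    strand = o_strand, width = motif_width, bound_ramp = o_ramp,
    depth_frac = o_dfrac, stringsAsFactors = FALSE)
  structure(list(gene_programme = gene_programme, tf_role = tf_role,
                 tf_genes = tf_genes, tad_classes = tad_classes,
                 peak_class = peak_class, motifs = motifs,
                 occurrences = occurrences, sequences = sequences,
                 cre = cre, embed_rates = embed_rates),
            class = "ef_truth")
}

consensus_pfm <- function(consensus) {
  w <- nchar(consensus)
  pfm <- matrix(1, 4, w, dimnames = list(BASES, NULL))
  idx <- match(strsplit(consensus, "")[[1]], BASES)
  pfm[cbind(idx, seq_len(w))] <- 18
  pfm
}

peak_tad_index <- function(genome) {
  peaks <- genome$peaks
  tad <- rep(NA_integer_, nrow(peaks))
  mid <- (peaks$start + peaks$end) %/% 2L
  for (i in seq_len(nrow(genome$tads))) {
    hit <- peaks$chrom == genome$tads$chrom[i] &
      mid >= genome$tads$start[i] & mid < genome$tads$end[i]
    tad[hit] <- i
  }
  # promoter peaks were placed over the first gene's TSS of each TAD
  is_prom <- rep(FALSE, nrow(peaks))
  for (i in seq_len(nrow(genome$tads))) {
    in_tad <- which(!is.na(tad) & tad == i)
    if (length(in_tad) > 0) is_prom[in_tad[1]] <- TRUE
  }
  list(tad = tad, is_promoter = is_prom)
}

gap_peaks_of <- function(genome, gap_gene) {
  g <- genome$genes[genome$genes$gene == gap_gene, ]
  tads <- genome$tads[genome$tads$chrom == g$chrom, ]
  tads <- tads[order(tads$start), ]
  after <- which(tads$end <= g$start)
  gs <- tads$end[max(after)]
  ge <- tads$start[min(which(tads$start >= g$end))]
  mid <- (genome$peaks$start + genome$peaks$end) %/% 2L
  genome$peaks$peak_id[genome$peaks$chrom == g$chrom & mid >= gs & mid < ge]
}

# Programme-specific mean normalized expression per sample group.
programme_means <- function(programme) {
  switch(programme,
    up_after_d3 = c(d0 = 300, d1 = 300, d2 = 360, d3 = 450,
                    d4p = 24000, d4n = 450, d5p = 48000, d5n = 450),
    gradual_down = c(d0 = 12000, d1 = 9000, d2 = 7500, d3 = 6000,
                     d4p = 180, d4n = 6000, d5p = 90, d5n = 4500),
    transient = c(d0 = 2400, d1 = 6000, d2 = 9000, d3 = 12000,
                  d4p = 300, d4n = 7500, d5p = 180, d5n = 4500),
    stable = c(d0 = 1000, d1 = 1000, d2 = 1000, d3 = 1000,
               d4p = 1000, d4n = 1000, d5p = 1000, d5n = 1000),
    stop("unknown programme: ", programme))
}

#' Simulate the time-course expression count matrix
#'
#' Negative-binomial counts around programme-specific mean trajectories:
#' days 0-3 unsorted, days 4-5 split into GFP-positive and GFP-negative
#' samples. Genes upregulated after day 3 have planted log2 fold changes
#' well above the differential-expression gate in every transition
#' contrast, with low but non-zero GFP-negative expression; stable genes
#' are high-mean, low-dispersion so they satisfy the housekeeping gates.
#'
#' @param truth an `ef_truth` from [simulate_truth()].
#' @param n_reps replicates per sample group (default 3; >= 2 required).
#' @param dispersion NB dispersion for programme genes (default 0.02).
#' @param stable_dispersion dispersion for stable genes (default 5e-4).
#' @param seed RNG seed.
#' @return An `ef_counts` object.
#' @export
simulate_expression <- function(truth, n_reps = 3L, dispersion = 0.005,
                                stable_dispersion = 5e-4, seed = 1L) {
  if (n_reps < 2) stop("n_reps must be >= 2 (differential expression needs replicates)")
  if (dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed + 202L)
  groups <- c("d0", "d1", "d2", "d3", "d4p", "d4n", "d5p", "d5n")
  ids <- unlist(lapply(groups, function(g) {
    d <- sub("^d([0-9]+).*$", "\\1", g)
    suff <- if (grepl("p$", g)) "p" else if (grepl("n$", g)) "n" else ""
    paste0("d", d, suff, "_r", seq_len(n_reps))
  }))
  genes <- names(truth$gene_programme)
  mat <- matrix(0L, length(genes), length(ids),
                dimnames = list(genes, ids))
  for (g in genes) {
    prog <- truth$gene_programme[g]
    mu <- programme_means(prog)
    disp <- if (prog == "stable") stable_dispersion else dispersion
    row <- unlist(lapply(groups, function(grp) {
      stats::rnbinom(n_reps, mu = mu[grp], size = 1 / disp)
    }))
    mat[g, ] <- as.integer(row)
  }
  ef_counts(mat)
}

#' Simulate per-day peak accessibility and per-bp tracks
#'
#' Peak-level raw signal follows a latent log2 trajectory per dynamic
#' class (opening peaks rise from day 3 to day 5 by well over the dynamic
#' gate) with log-normal multiplicative noise. Per-bp tracks carry each
#' peak's amplitude over its interval plus Poisson-like noise; bound
#' occurrences get a central depletion of `depth_frac x amplitude`
#' (scaled by the day's binding occupancy) with a 10% flanking
#' enrichment. Day 4 is deliberately absent from the grid.
#'
#' @param truth an `ef_truth`.
#' @param genome the matching [simulate_genome()] output.
#' @param seed RNG seed.
#' @param noise_sd log2-scale sd of peak-level noise (default 0.2).
#' @param pois_k Poisson sampling granularity for tracks (default 5;
#'   larger is less noisy).
#' @param base_lfc planted opening log2 amplitude change (default 2.8).
#' @param tracks whether to build per-bp tracks (default TRUE).
#' @return List with `signal` (peaks x days raw matrix, columns
#'   `r ATAC_DAYS`), `tracks` (named list of `ef_track` per day, or NULL),
#'   and `amplitude` (peaks x days latent per-bp amplitude).
#' @export
simulate_accessibility <- function(truth, genome, seed = 1L,
                                   noise_sd = 0.2, pois_k = 5,
                                   base_lfc = 2.8, tracks = TRUE) {
  set.seed(seed + 303L)
  peaks <- genome$peaks
  l0 <- log2(30)
  lat <- matrix(0, nrow(peaks), length(ATAC_DAYS),
                dimnames = list(peaks$peak_id, ATAC_DAYS))
  for (i in seq_len(nrow(peaks))) {
    cls <- truth$peak_class[as.character(peaks$peak_id[i])]
    lat[i, ] <- switch(cls,
      opening = l0 + base_lfc * OPEN_RAMP,
      closing = l0 + base_lfc * (1 - OPEN_RAMP),
      static = rep(l0 + 1.4, length(ATAC_DAYS)))
  }
  noise <- matrix(stats::rnorm(length(lat), 0, noise_sd), nrow(lat))
  signal <- 2^(lat + noise)
  amplitude <- 2^lat / 20
  track_list <- NULL
  if (tracks) {
    track_list <- lapply(seq_along(ATAC_DAYS), function(di) {
      values <- lapply(genome$chrom_lengths, function(n) rep(0.2, n))
      names(values) <- names(genome$chrom_lengths)
      for (i in seq_len(nrow(peaks))) {
        chrom <- peaks$chrom[i]
        idx <- (peaks$start[i] + 1L):peaks$end[i]
        values[[chrom]][idx] <- amplitude[i, di]
      }
      occ <- truth$occurrences
      for (k in seq_len(nrow(occ))) {
        if (occ$bound_ramp[k] == "none") next
        w <- BOUND_RAMPS[[occ$bound_ramp[k]]][di]
        if (w == 0) next
        pi <- match(occ$peak_id[k], as.character(peaks$peak_id))
        chrom <- peaks$chrom[pi]
        a <- amplitude[pi, di]
        d <- occ$depth_frac[k] * a * w
        centre <- peaks$start[pi] + occ$offset[k] + occ$width[k] %/% 2L
        cen_idx <- (centre - 12L + 1L):(centre + 12L)
        fl_idx <- c((centre - 72L + 1L):(centre - 12L),
                    (centre + 12L + 1L):(centre + 72L))
        fl_idx <- fl_idx[fl_idx > peaks$start[pi] & fl_idx <= peaks$end[pi]]
        values[[chrom]][cen_idx] <- pmax(values[[chrom]][cen_idx] - d, 0)
        values[[chrom]][fl_idx] <- values[[chrom]][fl_idx] + 0.1 * d
      }
      for (chrom in names(values)) {
        values[[chrom]] <- stats::rpois(length(values[[chrom]]),
                                        values[[chrom]] * pois_k) / pois_k
      }
      ef_track(values)
    })
    names(track_list) <- ATAC_DAYS
  }
  list(signal = signal, tracks = track_list, amplitude = amplitude)
}

#' Simulate a complete input bundle with planted ground truth
#'
#' One call producing everything the pipeline consumes: genome, truth
#' table, expression counts, peak accessibility and per-bp tracks.
#'
#' @param preset `"default"` (12 TADs, 4 genes and 24 peaks per TAD) or
#'   `"small"` (6 TADs, 3 genes, 10 peaks; no per-bp tracks are skipped).
#' @param seed master seed; all stage seeds derive from it.
#' @param tracks build per-bp tracks (default TRUE).
#' @return List with `genome`, `truth`, `counts`, `access` (from
#'   [simulate_accessibility()]).
#' @export
simulate_bundle <- function(preset = c("default", "small"), seed = 1L,
                            tracks = TRUE) {
  preset <- match.arg(preset)
  genome <- switch(preset,
    default = simulate_genome(n_tads = 12L, genes_per_tad = 4L,
                              peaks_per_tad = 24L, seed = seed),
    small = simulate_genome(n_tads = 6L, genes_per_tad = 3L,
                            peaks_per_tad = 10L, seed = seed,
                            tad_width = 9000L))
  truth <- simulate_truth(genome, seed = seed,
                          n_inert = if (preset == "small") 6L else 10L)
  counts <- simulate_expression(truth, seed = seed)
  access <- simulate_accessibility(truth, genome, seed = seed,
                                   tracks = tracks)
  list(genome = genome, truth = truth, counts = counts, access = access,
       preset = preset, seed = seed)
}

#' Write the planted truth as JSON
#'
#' Machine-readable ground truth so downstream predictions can be joined
#' back to what was planted.
#'
#' @param truth an `ef_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(gene_programme = as.list(truth$gene_programme),
              tf_role = as.list(truth$tf_role),
              peak_class = as.list(truth$peak_class),
              cre = as.list(truth$cre),
              embed_rates = truth$embed_rates,
              occurrences = truth$occurrences)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' GC fraction of sequences
#'
#' @param seqs character vector of DNA sequences.
#' @return Numeric vector of G+C fractions.
#' @export
gc_content <- function(seqs) {
  vapply(seqs, function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    mean(v %in% c("G", "C"))
  }, 1.0, USE.NAMES = FALSE)
}
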