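test_that("genome generation is deterministic and structurally sound", {
  g1 <- simulate_genome(n_tads = 4, genes_per_tad = 2, peaks_per_tad = 6,
                        seed = 5, n_chrom = 2)
  g2 <- simulate_genome(n_tads = 4, genes_per_tad = 2, peaks_per_tad = 6,
                        seed = 5, n_chrom = 2)
  expect_identical(g1, g2)
  g3 <- simulate_genome(n_tads = 4, genes_per_tad = 2, peaks_per_tad = 6,
                        seed = 6, n_chrom = 2)
  expect_false(identical(g1$sequences, g3$sequences))
  expect_equal(nrow(g1$tads), 4)
  expect_gt(length(g1$gap_genes), 0)
  # TADs non-overlapping per chromosome
  for (ch in unique(g1$tads$chrom)) {
    t <- g1$tads[g1$tads$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1) expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
  }
  # no peak straddles a TAD or gap boundary
  bounds <- sort(unique(c(g1$tads$start, g1$tads$end)))
  for (i in seq_len(nrow(g1$peaks))) {
    inside <- bounds > g1$peaks$start[i] & bounds < g1$peaks$end[i]
    expect_false(any(inside))
  }
  # sequences match peak widths
  expect_equal(unname(nchar(g1$sequences)),
               g1$peaks$end - g1$peaks$start)
  expect_error(simulate_genome(n_tads = 2, genes_per_tad = 2,
                               peaks_per_tad = 100, seed = 1),
               "too small")
  expect_error(simulate_genome(n_tads = 0), ">= 1")
})

test_that("planted truth embeds motifs preferentially by role", {
  g <- simulate_genome(seed = 2)
  tr <- simulate_truth(g, seed = 2)
  occ <- tr$occurrences
  occ$class <- tr$peak_class[occ$peak_id]
  role <- tr$tf_role[occ$tf]
  n_class <- table(tr$peak_class)
  rate <- function(rl, cl) {
    sum(role == rl & occ$class == cl) /
      (sum(names(tr$tf_role)[tr$tf_role == rl] |> length()) * n_class[cl])
  }
  # activators concentrate in opening peaks, repressors in closing peaks
  expect_gt(rate("activator", "opening"), rate("activator", "closing") + 0.5)
  expect_gt(rate("repressor", "closing"), rate("repressor", "opening") + 0.2)
  # every embedded occurrence carries its consensus (or reverse
  # complement) at the recorded offset
  for (i in sample(nrow(occ), 25)) {
    cons <- pfm_consensus(tr$motifs[[occ$motif_id[i]]]$pfm)
    if (occ$strand[i] == "-") cons <- revcomp(cons)
    expect_equal(unname(substr(tr$sequences[occ$peak_id[i]],
                               occ$offset[i] + 1,
                               occ$offset[i] + occ$width[i])),
                 cons)
  }
  # the designated CRE peak carries every activator motif
  acts <- names(tr$tf_role)[tr$tf_role == "activator"]
  for (gg in names(tr$cre)) {
    embedded <- occ$tf[occ$peak_id == tr$cre[[gg]]]
    expect_true(all(acts %in% embedded))
  }
})

test_that("expression counts follow the planted programmes", {
  g <- simulate_genome(n_tads = 4, genes_per_tad = 2, peaks_per_tad = 6,
                       seed = 3)
  tr <- simulate_truth(g, seed = 3, n_act = 2, n_rep = 2, n_inert = 2)
  # fixed seed reproduces the matrix exactly
  c1 <- simulate_expression(tr, seed = 9)
  c2 <- simulate_expression(tr, seed = 9)
  expect_identical(c1$counts, c2$counts)
  expect_error(simulate_expression(tr, n_reps = 1), "replicates")
  expect_error(simulate_expression(tr, dispersion = 0), "dispersion")
  # law of large numbers: at near-zero dispersion and many replicates the
  # sample means converge to the planted means
  c3 <- simulate_expression(tr, n_reps = 50, dispersion = 1e-3,
                            stable_dispersion = 1e-3, seed = 10)
  meta <- c3$meta
  for (prog in c("up_after_d3", "stable")) {
    gene <- names(tr$gene_programme)[tr$gene_programme == prog][1]
    mu <- eyefield:::programme_means(prog)
    d5p <- meta$sample_id[meta$day == 5 & meta$gfp == "positive"]
    expect_lt(abs(mean(c3$counts[gene, d5p]) / mu[["d5p"]] - 1), 0.05)
  }
  # stable genes satisfy the flatness gate for the large majority
  norm <- normalize_counts(c1)
  hk <- housekeeping_genes(norm, c1$meta)
  stable <- names(tr$gene_programme)[tr$gene_programme == "stable"]
  expect_gte(mean(stable %in% hk), 0.5)
})

test_that("accessibility dynamics and tracks express the planted classes", {
  b <- simulate_bundle("small", seed = 4)
  tr <- b$truth
  sig <- b$access$signal
  lr <- log2(sig[, "d5"]) - log2(sig[, "d3"])
  opening <- names(tr$peak_class)[tr$peak_class == "opening"]
  closing <- names(tr$peak_class)[tr$peak_class == "closing"]
  static <- names(tr$peak_class)[tr$peak_class == "static"]
  expect_gte(mean(lr[opening] > 1.5), 0.95)
  expect_gte(mean(lr[closing] < -1.5), 0.95)
  # static peaks: day differences centred at zero
  expect_lt(abs(mean(lr[static])), 0.15)
  # identical seed, identical tracks
  b2 <- simulate_bundle("small", seed = 4)
  expect_identical(b$access$tracks$d5$values, b2$access$tracks$d5$values)
})

test_that("truth tables serialize to machine-readable JSON", {
  g <- simulate_genome(n_tads = 4, genes_per_tad = 2, peaks_per_tad = 6,
                       seed = 3)
  tr <- simulate_truth(g, seed = 3, n_act = 2, n_rep = 2, n_inert = 2)
  path <- tempfile(fileext = ".json")
  write_truth(tr, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$gene_programme),
               tr$gene_programme[names(back$gene_programme)])
  expect_equal(length(back$occurrences), nrow(tr$occurrences))
  expect_equal(unlist(back$cre), tr$cre)
})
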