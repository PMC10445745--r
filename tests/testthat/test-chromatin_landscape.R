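test_that("consensus merging follows bedtools semantics", {
  d1 <- toy_peaks(0, 10)
  d2 <- toy_peaks(10, 20)
  cons <- merge_consensus(list(d1, d2))
  expect_equal(nrow(cons), 1)           # book-ended intervals merge
  expect_equal(c(cons$start, cons$end), c(0L, 20L))
  cons2 <- merge_consensus(list(toy_peaks(c(0, 7), c(5, 9))))
  expect_equal(nrow(cons2), 2)          # disjoint stay separate
  # three identical days collapse to one
  cons3 <- merge_consensus(list(d1, d1, d1))
  expect_equal(cons3[, c("start", "end")], d1[, c("start", "end")])
  # blacklist removal by any overlap
  cons4 <- merge_consensus(list(toy_peaks(c(0, 100), c(10, 120))),
                           blacklist = toy_peaks(105, 108))
  expect_equal(nrow(cons4), 1)
  expect_equal(cons4$end, 10L)
})

test_that("accessibility normalization reduces covariate trends and is scale invariant", {
  set.seed(21)
  n <- 200
  gc <- runif(n, 0.3, 0.7)
  width <- rep(400L, n)
  base <- matrix(2^rnorm(n * 3, 7, 0.3), n,
                 dimnames = list(seq_len(n), c("d0", "d3", "d5")))
  # no covariate variation: reduces to library scaling + log
  same <- normalize_accessibility(base, gc = rep(0.5, n), width = width)
  tot <- colSums(base)
  expect_equal(same,
               log2(sweep(base, 2, 100 * n / tot, "*") + 1),
               tolerance = 1e-12)
  # doubling one day's raw signal leaves its normalized values unchanged
  doubled <- base
  doubled[, "d5"] <- doubled[, "d5"] * 2
  expect_equal(normalize_accessibility(doubled, rep(0.5, n), width)[, "d5"],
               same[, "d5"], tolerance = 1e-9)
  # planted linear GC bias shrinks by >= 80 percent
  biased <- base * 2^(4 * (gc - 0.5))
  nb <- normalize_accessibility(biased, gc, width)
  r_before <- abs(cor(log2(biased[, 1] + 1), gc))
  r_after <- abs(cor(nb[, 1], gc))
  expect_lt(r_after, 0.2 * r_before)
  # mean preserved per day
  lb <- log2(sweep(biased, 2, 100 * n / colSums(biased), "*") + 1)
  expect_equal(colMeans(nb), colMeans(lb), tolerance = 1e-9)
  expect_error(normalize_accessibility(base, gc = rep(2, n), width), "gc")
})

test_that("annotation precedence is promoter > exonic > intronic > intergenic", {
  genes <- toy_gene(start = 5000L, end = 5900L, strand = "+")
  pk <- toy_peaks(c(4900, 5400, 9000, 5950),
                  c(5100, 5500, 9100, 6050))
  ann <- annotate_peaks(pk, genes, promoter_window = 100L)
  # peak 1 covers the TSS; peak 2 sits in the intron; peak 3 far away;
  # peak 4 overlaps the terminal exon only
  expect_equal(ann[1:3], c("promoter", "intronic", "intergenic"))
  # terminal exon region but outside promoter window
  pk4 <- toy_peaks(5700, 5800)
  expect_equal(annotate_peaks(pk4, genes, promoter_window = 100L), "exonic")
  # exon overlapping the promoter window resolves to promoter
  expect_equal(annotate_peaks(toy_peaks(5050, 5200), genes,
                              promoter_window = 100L), "promoter")
  # categories partition any peak universe
  set.seed(2)
  pk_many <- toy_peaks(seq(4000, 9000, by = 100),
                       seq(4080, 9080, by = 100))
  ann_many <- annotate_peaks(pk_many, genes, promoter_window = 150L)
  expect_equal(length(ann_many), nrow(pk_many))
  expect_true(all(ann_many %in% c("promoter", "exonic", "intronic",
                                  "intergenic")))
})

test_that("dynamic peak classes use strict log2 thresholds", {
  norm <- cbind(d3 = c(0, 0, 0, 0), d5 = c(2, 1.5, -2, 1.4))
  rownames(norm) <- 1:4
  dyn <- dynamic_peaks(norm, lfc_thresh = 1.5)
  expect_equal(dyn$dynamic_class, c("opening", "static", "closing",
                                    "static"))
  expect_equal(dyn$delta, c(2, 1.5, -2, 1.4))
  expect_error(dynamic_peaks(norm[, 1, drop = FALSE]), "both days")
})

test_that("TAD assignment synthesizes gaps, tiles, and classes regions", {
  tads <- data.frame(chrom = "chr1", start = c(0L, 2000L, 5000L),
                     end = c(1000L, 3000L, 6000L))
  genes <- rbind(toy_gene("gUp", start = 100L, end = 900L),
                 toy_gene("gGap", start = 1200L, end = 1900L),
                 toy_gene("gHk", start = 2100L, end = 2900L))
  peaks <- toy_peaks(c(0, 1500, 2500, 7000), c(200, 1700, 2700, 7200))
  gs <- list(ef_up = "gUp", ef_down = character(0), housekeeping = "gHk")
  asg <- assign_tads(tads, peaks, genes, gs)
  reg <- asg$regions
  # TAD + gap regions tile the TAD-spanned extent without overlap
  reg1 <- reg[order(reg$start), ]
  expect_equal(reg1$start[-1], reg1$end[-nrow(reg1)])
  expect_equal(sum(reg1$kind == "gap"), 2)
  # gene inside a gap classifies that gap from its own genes
  gap_id <- asg$gene_region[["gGap"]]
  expect_equal(reg$kind[reg$region_id == gap_id], "gap")
  expect_equal(reg$class[reg$region_id == asg$gene_region[["gUp"]]],
               "ef_up")
  expect_equal(reg$class[reg$region_id == asg$gene_region[["gHk"]]],
               "housekeeping")
  # peak midpoint on a TAD start belongs to that TAD (half-open)
  pk_edge <- toy_peaks(1900, 2100)  # midpoint 2000 == TAD2 start
  asg2 <- assign_tads(tads, pk_edge, genes, gs)
  tad2 <- reg$region_id[reg$start == 2000 & reg$kind == "tad"]
  expect_equal(unname(asg2$peak_region[1]), tad2)
  # peak outside the TAD-spanned extent has no region
  expect_true(is.na(asg$peak_region[["4"]]))
  # overlapping TADs rejected
  bad <- data.frame(chrom = "chr1", start = c(0L, 500L),
                    end = c(1000L, 1500L))
  expect_error(assign_tads(bad, peaks, genes, gs), "overlapping")
})

test_that("basal-plus-extension links peaks to genes with a 1 Mb cap", {
  genes <- rbind(toy_gene("gA", start = 50000L, end = 50900L),
                 toy_gene("gB", start = 60000L, end = 60900L))
  # peak 2 kb upstream of gA: inside its basal domain
  expect_equal(region_gene_associations(toy_peaks(47900, 48100),
                                        genes[1, ])$gene, "gA")
  # peak 2 Mb away: unlinked
  expect_equal(nrow(region_gene_associations(toy_peaks(2050000, 2050200),
                                             genes[1, ])), 0)
  # two genes 10 kb apart, peak between them links to both: each gene's
  # extension runs to the other's basal domain, so their domains overlap
  links <- region_gene_associations(toy_peaks(52000, 52200), genes)
  expect_setequal(links$gene, c("gA", "gB"))
  # extension stops at a neighbouring basal domain
  genes3 <- rbind(genes,
                  toy_gene("gC", start = 40000L, end = 40900L))
  links3 <- region_gene_associations(toy_peaks(40500, 40700), genes3)
  expect_true("gC" %in% links3$gene)
})

test_that("promoter group statistics use the Mann-Whitney U test", {
  a <- matrix(c(1, 2, 3), 3, 2)
  b <- matrix(c(4, 5, 6), 3, 2)
  st <- promoter_stats(a, b)
  # exact two-sided p for {1,2,3} vs {4,5,6}: U = 0, 2 * 1/20
  expect_equal(st$p_location, 0.1)
  expect_equal(st$median_mean_a, 2)
  expect_equal(st$median_mean_b, 5)
  # identical groups: no location shift
  st0 <- promoter_stats(a, a)
  expect_gt(st0$p_location, 0.99)
  # strongly shifted large groups: overwhelming significance
  set.seed(4)
  big_a <- matrix(rnorm(400, 0), 200, 2)
  big_b <- matrix(rnorm(400, 4), 200, 2)
  expect_lt(promoter_stats(big_a, big_b)$p_location, 1e-10)
  expect_error(promoter_stats(a[1, , drop = FALSE], b), ">= 2")
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  x <- c(1.2, 3.4, 0.7)
  y <- c(2.2, 5.1, 4.4)
  p_pkg <- eyefield:::mw_test(x, y)
  # enumerate all choose(6,3) assignments of the pooled values
  pool <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- combn(6, 3)
  us <- apply(combos, 2, function(idx) {
    xx <- pool[idx]
    yy <- pool[-idx]
    sum(outer(xx, yy, ">"))
  })
  # two-sided: double the smaller tail (no ties here)
  p_enum <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  expect_equal(p_pkg, min(p_enum, 1))
})
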