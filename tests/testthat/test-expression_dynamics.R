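test_that("size factors follow median-of-ratios with geometric mean 1", {
  # identical columns -> all factors 1
  m <- matrix(c(10, 5, 8, 10, 5, 8), 3,
              dimnames = list(paste0("g", 1:3), c("d0_r1", "d0_r2")))
  expect_equal(unname(size_factors(m)), c(1, 1), tolerance = 1e-12)
  # doubling a column doubles its factor relative to the other
  m2 <- m
  m2[, 2] <- m[, 1] * 2
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  # hand-computed 3x3: every gene row proportional to (1,2,3)
  m3 <- matrix(c(10, 5, 8, 20, 10, 16, 30, 15, 24), 3,
               dimnames = list(paste0("g", 1:3),
                               c("d0_r1", "d0_r2", "d0_r3")))
  f3 <- size_factors(m3)
  expect_equal(unname(f3 / f3[1]), c(1, 2, 3), tolerance = 1e-12)
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)
  # permutation of gene rows leaves factors unchanged
  expect_equal(size_factors(m3[c(3, 1, 2), ]), f3)
  # all-zero gene in one sample only: still fine; no gene covering all -> error
  m4 <- matrix(c(0, 1, 1, 0), 2,
               dimnames = list(c("g1", "g2"), c("d0_r1", "d0_r2")))
  expect_error(size_factors(m4), "pseudocount")
})

test_that("differential expression is antisymmetric and null on identical groups", {
  set.seed(11)
  norm <- matrix(rpois(60, 100), 10,
                 dimnames = list(paste0("g", 1:10),
                                 c(paste0("d0_r", 1:3), paste0("d3_r", 1:3))))
  a <- colnames(norm)[1:3]
  b <- colnames(norm)[4:6]
  de <- differential_expression(norm, a, b)
  de_swap <- differential_expression(norm, b, a)
  expect_equal(de$log2fc, -de_swap$log2fc)
  expect_equal(de$pvalue, de_swap$pvalue, tolerance = 1e-9)
  # duplicated group: fold changes exactly zero, p-values ~1
  norm2 <- cbind(norm[, a], norm[, a])
  colnames(norm2) <- c(a, b)
  de0 <- differential_expression(norm2, a, b)
  expect_equal(de0$log2fc, rep(0, 10))
  expect_true(all(de0$pvalue > 0.999))
  expect_error(differential_expression(norm, a[1], b), "replicates")
})

test_that("Benjamini-Hochberg matches the hand-computed toy vector", {
  # computed by hand: p * n / rank with cumulative minimum from the right
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), method = "BH"),
               c(0.04, 0.04, 0.04, 0.5))
  set.seed(3)
  norm <- matrix(rpois(40, 50), 4,
                 dimnames = list(paste0("g", 1:4),
                                 c(paste0("d0_r", 1:5), paste0("d3_r", 1:5))))
  de <- differential_expression(norm, colnames(norm)[1:5],
                                colnames(norm)[6:10])
  expect_equal(de$fdr, p.adjust(de$pvalue, method = "BH"))
})

test_that("planted fold changes are recovered at triplicate scale", {
  # 4-fold planted gene at low dispersion: log2fc near 2, fdr < 0.001
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    mu <- c(rep(500, 49), 500)
    mat <- sapply(1:6, function(j) {
      m <- mu
      if (j > 3) m[50] <- m[50] * 4
      rnbinom(50, mu = m, size = 1 / 0.003)
    })
    dimnames(mat) <- list(paste0("g", 1:50),
                          c(paste0("d0_r", 1:3), paste0("d3_r", 1:3)))
    de <- differential_expression(mat, colnames(mat)[1:3],
                                  colnames(mat)[4:6])
    row <- de[de$gene == "g50", ]
    if (row$log2fc > 1.8 && row$log2fc < 2.2 && row$fdr < 0.001) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)
})

test_that("EF gating intersects all contrasts with strict thresholds", {
  genes <- paste0("g", 1:4)
  tab <- function(lfc, fdr) {
    data.frame(gene = genes, log2fc = lfc, pvalue = fdr, fdr = fdr)
  }
  # g1 passes everywhere; g2 passes 2 of 3; g3 sits exactly on the
  # thresholds (excluded: strict inequalities); g4 is downregulated
  de <- list(
    a = tab(c(3, 3, 1.5, -3), c(1e-5, 1e-5, 0.001, 1e-5)),
    b = tab(c(3, 3, 1.5, -3), c(1e-5, 1e-5, 0.001, 1e-5)),
    c = tab(c(3, 0, 1.5, -3), c(1e-5, 0.5, 0.001, 1e-5)))
  gs <- call_ef_genes(de)
  expect_equal(gs$ef_up, "g1")
  expect_equal(gs$ef_down, "g4")
  expect_length(intersect(gs$ef_up, gs$ef_down), 0)
  expect_error(call_ef_genes(list()), "missing contrast")
})

test_that("housekeeping gating enforces per-comparison flatness and mean", {
  ids <- c(paste0("d", 0:3, "_r1"), "d4p_r1", "d4n_r1", "d5p_r1")
  meta <- parse_sample_meta(ids)
  norm <- rbind(
    flat100 = rep(100, 7),
    flat10 = rep(10, 7),
    one_jump = c(100, 100, 100 * 2^0.2, 100, 100, 100, 100))
  colnames(norm) <- ids
  hk <- housekeeping_genes(norm, meta)
  expect_true("flat100" %in% hk)
  expect_false("flat10" %in% hk)     # mean below 30
  expect_false("one_jump" %in% hk)   # a single successive-day jump disqualifies
  # GFP-negative day-4/5 samples are ignored (GFP+ branch is used)
  norm2 <- norm
  norm2["flat100", "d4n_r1"] <- 1e6
  expect_true("flat100" %in% housekeeping_genes(norm2, meta))
})

test_that("stage overlaps are exact set arithmetic", {
  expect_equal(stage_overlap(c("a", "b"), c("a", "b"))$n_overlap, 2)
  expect_equal(stage_overlap(c("a"), c("b"))$n_overlap, 0)
  ov <- stage_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(c(ov$n_a, ov$n_b, ov$n_overlap), c(3, 3, 2))
  expect_setequal(ov$overlap, c("b", "c"))
})
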