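test_that("PWM p-values from the DP match exhaustive word enumeration", {
  set.seed(14)
  for (w in c(3, 5)) {
    pfm <- matrix(rpois(4 * w, 4) + 1, 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pwm_from_pfm(pfm)
    dp <- pwm_score_pvalues(pwm)
    # enumerate all 4^w words under the uniform background using the same
    # integer-rounded scores
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    iscores <- apply(words, 1, function(idx) {
      sum(dp$imat[cbind(idx, seq_len(w))])
    })
    for (s in unique(iscores)) {
      expect_equal(dp$pvals[s + 1], mean(iscores >= s), tolerance = 1e-12)
    }
  }
})

test_that("scanning finds planted consensus occurrences on both strands", {
  ms <- toy_motifs("ACGTTTGA", tf = "tfX")
  cons <- "ACGTTTGA"
  set.seed(3)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  seqs <- c(p1 = paste0(bg(40), cons, bg(40)),
            p2 = paste0(bg(20), revcomp(cons), bg(60)))
  occ <- scan_motifs(ms, seqs)
  o1 <- occ[occ$peak_id == "p1", ]
  expect_equal(o1$offset, 40L)
  expect_equal(o1$strand, "+")
  expect_equal(o1$pvalue, min(occ$pvalue))
  o2 <- occ[occ$peak_id == "p2", ]
  expect_equal(o2$offset, 20L)
  expect_equal(o2$strand, "-")
  # strand symmetry: reverse-complementing a sequence mirrors positions
  # and swaps strands but keeps the (count, p-value) set
  rcseqs <- c(p1 = revcomp(seqs[["p1"]]))
  occ_rc <- scan_motifs(ms, rcseqs)
  expect_equal(nrow(occ_rc), nrow(o1))
  expect_equal(sort(occ_rc$pvalue), sort(o1$pvalue))
  expect_equal(occ_rc$offset, nchar(seqs[["p1"]]) - o1$offset - 8L)
  expect_equal(occ_rc$strand, "-")
  # motif wider than the sequence: no occurrences, no error
  expect_equal(nrow(scan_motifs(ms, c(tiny = "ACGT"))), 0)
  # windows containing N are skipped
  seq_n <- c(p3 = paste0(bg(10), "ACGTNTGA", bg(10)))
  occ_n <- scan_motifs(ms, seq_n)
  expect_false(any(occ_n$offset == 10))
})

test_that("motif presence collapses multiple motifs per TF", {
  occ <- data.frame(peak_id = c("1", "1", "2"),
                    motif_id = c("M_a_1", "M_a_2", "M_b"),
                    tf = c("tfA", "tfA", "tfB"),
                    stringsAsFactors = FALSE)
  pres <- motif_presence(occ, peak_ids = c("1", "2", "3"))
  expect_equal(dim(pres), c(3L, 2L))
  expect_equal(pres["1", "tfA"], 1L)
  expect_equal(pres["2", "tfA"], 0L)
  expect_equal(pres["3", "tfB"], 0L)
})

test_that("expressed TFs require mean normalized expression strictly above 50", {
  ids <- c(paste0("d", 0:3, "_r1"), paste0("d", 0:3, "_r2"))
  meta <- parse_sample_meta(ids)
  norm <- rbind(peaky = c(10, 10, 60, 10, 10, 10, 60, 10),
                at50 = rep(50, 8),
                just_below = rep(49.9, 8))
  colnames(norm) <- ids
  tf_genes <- c(tfPeak = "peaky", tfFifty = "at50", tfLow = "just_below")
  expect_equal(expressed_tfs(norm, meta, tf_genes), "tfPeak")
  expect_warning(
    expressed_tfs(norm, meta, c(tf_genes, tfGone = "absent")),
    "without expression")
})

test_that("hypergeometric enrichment matches exact tail sums", {
  pres <- matrix(0L, 20, 1, dimnames = list(1:20, "tfA"))
  pres[1:10, 1] <- 1L  # motif in all 10 signal peaks, none of background
  enr <- motif_enrichment(pres, signal_peaks = 1:10,
                          background_peaks = 11:20)
  expect_equal(enr$pvalue, 1 / choose(20, 10), tolerance = 1e-12)
  # equal proportions: odds ratio 1, unremarkable p
  pres2 <- matrix(0L, 20, 1, dimnames = list(1:20, "tfA"))
  pres2[c(1:5, 11:15), 1] <- 1L
  enr2 <- motif_enrichment(pres2, 1:10, 11:20)
  expect_equal(enr2$odds_ratio, 1)
  expect_gte(enr2$pvalue, 0.5)
  # implementation equals explicit tail enumeration on small universes
  set.seed(8)
  pres3 <- matrix(rbinom(30, 1, 0.4), 30, 1,
                  dimnames = list(1:30, "tfA"))
  enr3 <- motif_enrichment(pres3, 1:12, 13:30)
  a <- sum(pres3[1:12, 1])
  K <- sum(pres3[, 1])
  tail_sum <- sum(dhyper(a:min(12, K), K, 30 - K, 12))
  expect_equal(enr3$pvalue, tail_sum, tolerance = 1e-12)
  # signal peaks are removed from the background before testing
  enr4 <- motif_enrichment(pres3, 1:12, 1:30)
  expect_equal(enr4$pvalue, enr3$pvalue)
  expect_error(motif_enrichment(pres3, 1:30, 1:30), "empty background")
})

test_that("the logistic motif model recovers separating features", {
  set.seed(31)
  n <- 120
  labels <- rep(c("opening", "closing"), each = n / 2)
  pres <- cbind(
    sep = as.integer(labels == "opening"),              # perfect separator
    anti = as.integer(labels == "closing"),
    noise1 = rbinom(n, 1, 0.5),
    noise2 = rbinom(n, 1, 0.5))
  rownames(pres) <- seq_len(n)
  fit <- fit_motif_logit(pres, labels, seed = 1)
  expect_gt(fit$coefficients[["sep"]], 0)
  expect_lt(fit$coefficients[["anti"]], 0)
  expect_gt(abs(fit$coefficients[["sep"]]),
            max(abs(fit$coefficients[c("noise1", "noise2")])))
  expect_gt(fit$auc_cv, 0.95)
  expect_error(fit_motif_logit(pres, rep("opening", n)), "single class")
  few <- c(1:15, 61:75)
  expect_error(fit_motif_logit(pres[few, ], labels[few],
                               min_per_class = 20), ">= 20")
})

test_that("label permutation shrinks logistic coefficients toward zero", {
  set.seed(32)
  n <- 2000
  pres <- matrix(rbinom(n * 4, 1, 0.5), n,
                 dimnames = list(seq_len(n), paste0("tf", 1:4)))
  labels <- sample(rep(c("opening", "closing"), each = n / 2))
  fit <- fit_motif_logit(pres, labels, seed = 2)
  expect_lt(max(abs(fit$coefficients)), 0.1)
})
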