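test_that("footprint metrics match closed-form expectations", {
  # flat signal: flanking equals the constant, depth exactly 0
  m <- footprint_metrics(rep(2.5, 208), width = 8)
  expect_equal(m$flanking_accessibility, 2.5)
  expect_equal(m$footprint_depth, 0)
  # unit flanks, zero over the 24-bp centre: depth exactly -1
  v <- rep(1, 208)
  centre <- 100 + 4  # halfwidth + floor(width/2), 0-based
  v[(centre - 12 + 1):(centre + 12)] <- 0
  m2 <- footprint_metrics(v, width = 8)
  expect_equal(m2$flanking_accessibility, 1)
  expect_equal(m2$footprint_depth, -1)
  # piecewise signal: centre mean 0.4, flank mean 1.2 -> depth -0.8
  v3 <- rep(0, 208)
  v3[(centre - 12 + 1):(centre + 12)] <- 0.4
  v3[(centre - 72 + 1):(centre - 12)] <- 1.2
  v3[(centre + 12 + 1):(centre + 72)] <- 1.2
  m3 <- footprint_metrics(v3, width = 8)
  expect_equal(m3$flanking_accessibility, 1.2)
  expect_equal(m3$footprint_depth, -0.8)
  # window too short for centre + flanks
  expect_error(footprint_metrics(rep(1, 100), width = 8), "too short")
  # change between days is a plain difference
  d <- delta_metrics(m3, m2)
  expect_equal(d$d_footprint_depth, -1 - (-0.8))
  expect_equal(d$d_flanking_accessibility, 1 - 1.2)
})

test_that("aggregate profiles average windows and flip minus-strand ones", {
  len <- 1000L
  v <- seq_len(len) / len  # strictly increasing ramp
  tr <- ef_track(list(chr1 = v))
  occ1 <- data.frame(chrom = "chr1", start = 400L, end = 408L,
                     strand = "+")
  prof <- aggregate_profile(tr, occ1)
  expect_equal(prof$n_occurrences, 1)
  expect_equal(prof$values, track_query(tr, "chr1", 300, 508))
  # two occurrences: positionwise mean
  occ2 <- rbind(occ1, data.frame(chrom = "chr1", start = 600L,
                                 end = 608L, strand = "+"))
  prof2 <- aggregate_profile(tr, occ2)
  expect_equal(prof2$values,
               (track_query(tr, "chr1", 300, 508) +
                  track_query(tr, "chr1", 500, 708)) / 2)
  # minus strand reverses the window, so a ramp flips to decreasing
  occ3 <- occ1
  occ3$strand <- "-"
  prof3 <- aggregate_profile(tr, occ3)
  expect_equal(prof3$values, rev(prof$values))
  # associativity: aggregate of aggregates equals the pooled aggregate
  half <- (prof$values + prof3$values) / 2
  prof_both <- aggregate_profile(tr, rbind(occ1, occ3))
  expect_equal(prof_both$values, half)
  # windows beyond the chromosome are skipped and counted
  occ4 <- rbind(occ1, data.frame(chrom = "chr1", start = 50L, end = 58L,
                                 strand = "+"))
  prof4 <- aggregate_profile(tr, occ4)
  expect_equal(prof4$n_skipped, 1)
  expect_equal(prof4$values, prof$values)
})

test_that("occurrence scores are monotone in depletion and zero at the floor", {
  mk_track <- function(central) {
    v <- rep(1, 600)
    centre <- 300 + 4
    v[(centre - 12 + 1):(centre + 12)] <- central
    ef_track(list(chr1 = v))
  }
  occs <- data.frame(chrom = "chr1", start = c(300L, 300L),
                     end = c(308L, 308L), strand = "+",
                     motif_id = "M1", llr_score = c(5, 10))
  # zero depletion + minimal llr -> score exactly 0
  sc0 <- occurrence_scores(list(d0 = mk_track(1)), occs)
  expect_equal(sc0$score_d0[1], 0)
  # fixed llr, deeper depletion -> strictly larger score
  sc_shallow <- occurrence_scores(list(d0 = mk_track(0.6)), occs)
  sc_deep <- occurrence_scores(list(d0 = mk_track(0.1)), occs)
  expect_gt(sc_deep$score_d0[1], sc_shallow$score_d0[1])
  # match term uses min-max scaled llr
  expect_equal(sc0$score_d0[2] - sc0$score_d0[1], 0.3)
})

test_that("bound classification separates a constructed bimodal mixture", {
  set.seed(6)
  scores <- c(rnorm(40, 0, 0.05), rnorm(40, 1, 0.05))
  bound <- classify_bound(scores)
  expect_equal(unname(bound), rep(c(FALSE, TRUE), each = 40))
  expect_warning(b2 <- classify_bound(rep(0.3, 25)), "unbound")
  expect_false(any(b2))
  expect_error(classify_bound(scores[1:10]), ">= 20")
})

test_that("differential binding deltas are antisymmetric and standardized", {
  set.seed(7)
  scores <- data.frame(
    occurrence_id = 1:60,
    motif_id = rep(c("M1", "M2", "M3"), each = 20),
    score_d3 = rnorm(60),
    score_d5 = rnorm(60))
  scores$score_d5[scores$motif_id == "M1"] <-
    scores$score_d3[scores$motif_id == "M1"] + 2
  db <- differential_binding(scores, "d3", "d5")
  expect_equal(db$motif_id[which.max(db$z)], "M1")
  expect_equal(mean(db$z), 0, tolerance = 1e-12)
  expect_equal(sd(db$z), 1, tolerance = 1e-12)
  db_rev <- differential_binding(scores, "d5", "d3")
  expect_equal(db_rev$delta, -db$delta)
  expect_equal(db_rev$z, -db$z)
  # identical days: all deltas zero
  scores$score_d5 <- scores$score_d3
  db0 <- differential_binding(scores, "d3", "d5")
  expect_equal(db0$delta, rep(0, 3))
  # low-occurrence motifs flagged
  db_small <- differential_binding(scores[c(1:5, 21:40, 41:60), ],
                                   "d3", "d5")
  expect_true(db_small$low_confidence[db_small$motif_id == "M1"])
})

test_that("footprint-score trajectories correlate with TF expression", {
  expr <- rbind(tfA = c(1, 2, 3, 4, 5))
  colnames(expr) <- paste0("d", c(0, 1, 2, 3, 5))
  scores <- data.frame(occurrence_id = 1:2, motif_id = "M_A")
  for (i in seq_along(colnames(expr))) {
    scores[[paste0("score_", colnames(expr)[i])]] <-
      c(expr[1, i], 6 - expr[1, i])  # one tracking, one anti-tracking
  }
  fc <- footprint_expression_correlation(scores, c(M_A = "tfA"), expr)
  expect_equal(fc$n, 2)
  expect_equal(fc$median_r, 0)  # median of r = +1 and r = -1
  fc1 <- footprint_expression_correlation(scores[1, ], c(M_A = "tfA"),
                                          expr)
  expect_equal(fc1$median_r, 1)
  # constant trajectories are dropped
  scores2 <- scores
  for (cn in grep("^score_", names(scores2), value = TRUE)) {
    scores2[[cn]][2] <- 1
  }
  fc2 <- footprint_expression_correlation(scores2, c(M_A = "tfA"), expr)
  expect_equal(fc2$n, 1)
})

test_that("planted footprint depth is recovered from simulated tracks", {
  b <- simulate_bundle("small", seed = 11)
  occ <- b$truth$occurrences
  occ <- occ[occ$bound_ramp == "act", ]
  peaks <- b$genome$peaks
  pidx <- match(occ$peak_id, as.character(peaks$peak_id))
  occ$chrom <- peaks$chrom[pidx]
  occ$start <- peaks$start[pidx] + occ$offset
  occ$end <- occ$start + occ$width
  tr <- b$access$tracks$d5
  got <- vapply(seq_len(nrow(occ)), function(i) {
    centre <- occ$start[i] + 4L
    v <- track_query(tr, occ$chrom[i], centre - 72, centre + 72)
    footprint_metrics(v, centre = 72)$footprint_depth
  }, 1.0)
  amp <- b$access$amplitude[occ$peak_id, "d5"]
  planted <- occ$depth_frac * amp  # full occupancy on day 5
  # measured depth is -(1.1 x planted): flanks carry a 10% enrichment
  expect_equal(mean(got / planted), -1.1, tolerance = 0.15)
})
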