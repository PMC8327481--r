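track_from <- function(df, lengths) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
  signal_track(gr, Seqinfo(names(lengths), unname(lengths)))
}

test_that("mean score over intervals is the length-weighted per-base mean", {
  tr <- track_from(data.frame(chrom = "chr1", start = 1, end = 100,
                              score = 5), c(chr1 = 200L))
  iv <- GRanges("chr1", IRanges(11, 60))
  expect_equal(mean_score_over_interval(tr, iv), 5)

  # [0,10)=2, [10,20)=4 in 0-based terms; mean over [5,15) is 3.0
  tr2 <- track_from(data.frame(chrom = "chr1", start = c(1, 11),
                               end = c(10, 20), score = c(2, 4)),
                    c(chr1 = 30L))
  expect_equal(mean_score_over_interval(tr2, GRanges("chr1", IRanges(6, 15))),
               3.0)
  # uncovered bases count as zero
  expect_equal(mean_score_over_interval(tr2, GRanges("chr1", IRanges(11, 30))),
               4 * 10 / 20)
  expect_error(mean_score_over_interval(tr2, GRanges("chrX", IRanges(1, 5))),
               "no data")
})

test_that("mean score matches a per-base summation oracle on random tracks", {
  set.seed(99)
  starts <- seq(1, 991, by = 10)
  tr <- track_from(data.frame(chrom = "chr1", start = starts,
                              end = starts + 9,
                              score = rnorm(length(starts))),
                   c(chr1 = 1000L))
  per_base <- as.numeric(tr[["chr1"]])
  for (i in 1:20) {
    a <- sample(900, 1)
    b <- a + sample(50, 1)
    got <- mean_score_over_interval(tr, GRanges("chr1", IRanges(a, b)))
    expect_equal(got, mean(per_base[a:b]), tolerance = 1e-9)
  }
})

test_that("signal_track rejects overlapping intervals and missing chromosomes", {
  si <- Seqinfo("chr1", 100L)
  expect_error(signal_track(GRanges("chr1", IRanges(c(1, 5), c(10, 15)),
                                    score = c(1, 2)), si), "non-overlapping")
  expect_error(signal_track(GRanges("chr2", IRanges(1, 5), score = 1), si),
               "missing from seqinfo")
})

test_that("scores_by_group stratifies by mismatch and adds a background group", {
  si <- c(chr1 = 5000L)
  hits <- GRanges("chr1", IRanges(seq(100, by = 100, length.out = 8),
                                  width = 19),
                  mismatch_count = rep(0:3, 2),
                  seqinfo = Seqinfo("chr1", si))
  tr0 <- flat_track(si, 0)
  sg0 <- scores_by_group(tr0, hits, background_n = 50, seed = 1)
  expect_equal(sg0$summary$median, rep(0, 5))
  expect_equal(sg0$summary$n, c(2L, 2L, 2L, 2L, 50L))
  expect_equal(sg0$summary$group, c("0MM", "1MM", "2MM", "3MM", "Total"))
})

test_that("synthetic fidelity-decaying signal yields monotone group medians", {
  cfg <- simulation_config(
    seed = 13, n_chrom = 2L, chrom_length = 80000L,
    planted_groups = c(25L, 25L, 25L, 25L), n_mite = 0L, n_solo = 0L,
    element_spacing = c(600L, 800L), blacklist_fraction = 0,
    peak_fraction = rep(1, 4), n_offtarget = 0L,
    signal = list(S0 = 100, decay = 0.5, sigma = 5,
                  position_effects = NULL),
    expression = list(n_background_genes = 0L))
  loci <- generate_loci(cfg)
  chip <- generate_chip(loci)
  sg <- scores_by_group(chip$track, truth_hits(loci), background_n = 200,
                        seed = 2)
  med <- sg$summary$median[match(c("0MM", "1MM", "2MM", "3MM", "Total"),
                                 sg$summary$group)]
  expect_true(all(diff(med[1:4]) < 0))
  expect_equal(med[1:4], 100 * 0.5^(0:3), tolerance = 0.15)
  expect_lt(abs(med[5]), 2)
  # adjacent groups separate significantly
  for (k in 1:3) {
    p <- rank_sum_test(sg$scores[[k]], sg$scores[[k + 1]])$p.value
    expect_lt(p, 0.01)
  }
})

test_that("rank_sum_test handles identity, exact enumeration and ties", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)

  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p.value, 0.1)
  expect_equal(sep$method, "exact enumeration")
  # independent reference: wilcox.test exact branch (no ties)
  expect_equal(sep$p.value,
               wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value)

  tied <- rank_sum_test(c(1, 2), c(1, 2))
  expect_equal(tied$p.value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("rank_sum_test exact p agrees with wilcox.test on random small samples", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- round(rnorm(m), 2); y <- round(rnorm(n, 0.5), 2)
    if (anyDuplicated(c(x, y))) next
    expect_equal(rank_sum_test(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("exact and normal-approximation branches agree at boundary sizes", {
  set.seed(8)
  for (i in 1:30) {
    x <- rnorm(6); y <- rnorm(6, runif(1, -1, 1))
    p_exact <- rank_sum_test(x, y, exact_limit = 12)$p.value
    p_approx <- rank_sum_test(x, y, exact_limit = 0)$p.value
    expect_lt(abs(p_exact - p_approx), 0.05)
  }
})

sub_elements <- function(profiles, mm, scores_len = 19L, chrom = "chr1",
                         spacing = 1000L) {
  n <- length(profiles)
  starts <- seq(1000, by = spacing, length.out = n)
  hits <- GRanges(chrom, IRanges(starts, width = 19L), strand = "+",
                  mismatch_count = as.integer(mm),
                  matched_seq = ITR_CORE_MOTIF, profile = profiles,
                  seqinfo = Seqinfo(chrom, as.integer(starts[n] + 2000)))
  pair_itrs(hits)
}

test_that("substitution effects group 1MM solos and apply the frequency filter", {
  # 50 solos sharing one substitution -> frequency 100%
  el <- sub_elements(c(rep("", 5), rep("17:C>T", 50)),
                     c(rep(0, 5), rep(1, 50)))
  tr <- flat_track(c(chr1 = 57000L), 1)
  se <- substitution_effects(tr, el)
  expect_equal(nrow(se), 1L)
  expect_equal(se$frequency, 100)
  expect_equal(se$position, 17L)
  expect_equal(attr(se, "total_frequency"), 100)

  # frequency exactly at the cutoff is kept; below is dropped
  profs <- c(rep("", 3), rep("17:C>T", 97), rep("2:G>A", 2), "4:G>A")
  el2 <- sub_elements(profs, c(rep(0, 3), rep(1, 100)))
  tr2 <- flat_track(c(chr1 = 110000L), 1)
  se2 <- substitution_effects(tr2, el2, min_frequency = 2)
  expect_setequal(se2$position, c(17L, 2L))   # 1% group at position 4 dropped
  expect_equal(se2$frequency[se2$position == 2L], 2)
  expect_equal(attr(se2, "total_frequency"), 100)
  expect_error(substitution_effects(tr, sub_elements("17:C>T", 1)),
               "no 0MM solo")
})

test_that("a planted position-17 affinity drop is recovered within 20 percent", {
  cfg <- simulation_config(
    seed = 17, n_chrom = 2L, chrom_length = 120000L,
    planted_groups = c(50L, 150L, 0L, 0L), n_mite = 0L, n_solo = 0L,
    element_spacing = c(600L, 800L), blacklist_fraction = 0,
    substitution_spectrum = data.frame(
      position = c(17L, 14L, 8L), to = c("T", "C", "C"),
      weight = c(0.34, 0.33, 0.33)),
    peak_fraction = rep(1, 4), n_offtarget = 0L,
    signal = list(S0 = 100, decay = 1, sigma = 2,
                  position_effects = c(`17` = 1 / 6)),
    expression = list(n_background_genes = 0L))
  loci <- generate_loci(cfg)
  chip <- generate_chip(loci)
  el <- pair_itrs(truth_hits(loci))
  se <- substitution_effects(chip$track, el)
  i17 <- which(se$position == 17L)
  expect_length(i17, 1L)
  expect_equal(se$fold_change[i17], 6, tolerance = 0.2)
  expect_true(all(se$fold_change[i17] > se$fold_change[-i17]))
  expect_lt(se$p.value[i17], 1e-6)
  expect_equal(attr(se, "total_frequency"), 100)
})
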