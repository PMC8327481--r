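si_10k <- Seqinfo(seqnames = "chr1", seqlengths = 10000L)

gr_on <- function(start, end, si = si_10k, chrom = "chr1") {
  GRanges(chrom, IRanges(start, end), seqinfo = si)
}

test_that("extend_intervals grows both sides and clips at chromosome bounds", {
  # spec'd in 0-based half-open terms: [1000,1100) + 500 -> [500,1600)
  expect_equal(ranges(extend_intervals(gr_on(1001, 1100))),
               IRanges(501, 1600))
  # [100,200) + 500 -> [0,700), clipped at the chromosome start
  expect_equal(ranges(extend_intervals(gr_on(101, 200))),
               IRanges(1, 700))
  expect_equal(ranges(extend_intervals(gr_on(9801, 9900))),
               IRanges(9301, 10000))
  expect_equal(extend_intervals(gr_on(1001, 1100), 0), gr_on(1001, 1100))
  expect_error(extend_intervals(GRanges("chrZ", IRanges(1, 10))),
               "unknown chromosome")
  expect_error(extend_intervals(gr_on(1, 10), -1), ">= 0")
})

test_that("peak/ITR overlap uses >=1 bp intersection of extended peaks", {
  itr <- gr_on(5001, 5019)
  peak_on <- gr_on(5005, 5014)
  v <- overlap_peaks_itrs(peak_on, itr)
  expect_equal(v$n_peaks_with_itr, 1L)
  expect_equal(v$n_itrs_in_peaks, 1L)

  # extended peak [2001,3100] ends 1 bp before an ITR starting at 3101
  near <- gr_on(2501, 2600)
  itr2 <- gr_on(3101, 3119)
  v2 <- overlap_peaks_itrs(near, itr2)
  expect_equal(v2$n_peaks_with_itr, 0L)
  expect_equal(v2$n_itrs_in_peaks, 0L)
  # one bp closer and they touch
  v3 <- overlap_peaks_itrs(gr_on(2502, 2601), itr2)
  expect_equal(v3$n_peaks_with_itr, 1L)
})

test_that("planted peak/ITR overlap counts match construction", {
  si <- Seqinfo("chr1", 2000000L)
  itr_starts <- seq(10000, by = 15000, length.out = 100)
  itrs <- GRanges("chr1", IRanges(itr_starts, width = 19), seqinfo = si)
  peaked <- itr_starts[1:80]
  off <- seq(1600000, by = 20000, length.out = 5)
  peaks <- GRanges("chr1", IRanges(c(peaked - 150, off), width = 301),
                   seqinfo = si)
  v <- overlap_peaks_itrs(peaks, itrs)
  expect_equal(v$n_peaks, 85L)
  expect_equal(v$n_peaks_with_itr, 80L)
  expect_equal(v$n_itrs, 100L)
  expect_equal(v$n_itrs_in_peaks, 80L)
})

simple_genes <- function() {
  # gene on +: span 10000-12000, exons 10000-10200 and 11800-12000
  # gene on -: span 30000-32000 (TSS at 32000)
  ex <- c(GRanges("chr1", IRanges(c(10000, 11800), c(10200, 12000)),
                  strand = "+", gene_id = "gplus"),
          GRanges("chr1", IRanges(c(30000, 31800), c(30200, 32000)),
                  strand = "-", gene_id = "gminus"))
  gene_models(ex)
}

peak_at <- function(pos) {
  GRanges("chr1", IRanges(pos - 50, pos + 50), summit = pos,
          seqinfo = Seqinfo("chr1", 100000L))
}

test_that("summit annotation follows the TSS>TTS>exon>intron priority", {
  genes <- simple_genes()
  ann <- function(pos) as.character(annotate_summits(peak_at(pos), genes))
  expect_equal(ann(10100), "TSS")      # in exon 1 but within TSS window
  expect_equal(ann(11000), "intron")
  expect_equal(ann(11900), "TTS")      # in exon 2 but within TTS window
  expect_equal(ann(11500), "intron")
  expect_equal(ann(50000), "intergenic")
  expect_equal(ann(9800), "TSS")       # 200 bp upstream of the + TSS
  expect_equal(ann(8999), "intergenic")# just past the 1000-bp TSS window
  expect_equal(ann(32200), "TSS")      # upstream of the - strand TSS
  expect_equal(ann(29900), "TTS")      # downstream of the - strand TTS
})

test_that("exonic summits outside TSS/TTS windows are exonic", {
  ex <- GRanges("chr1", IRanges(c(10000, 14800), c(10200, 15000)),
                strand = "+", gene_id = "wide")
  genes <- gene_models(ex)
  expect_equal(as.character(annotate_summits(peak_at(14850), genes)), "exon")
  expect_equal(as.character(annotate_summits(peak_at(12000), genes)),
               "intron")
})

test_that("summit annotation is invariant to gene input order", {
  genes_fwd <- simple_genes()
  ex_rev <- rev(unlist(genes_fwd$exons))
  mcols(ex_rev)$gene_id <- names(ex_rev)
  names(ex_rev) <- NULL
  genes_rev <- gene_models(ex_rev)
  peaks <- peak_at(c(10100, 11000, 11900, 50000, 9800))
  mcols(peaks)$summit <- c(10100, 11000, 11900, 50000, 9800)
  expect_equal(annotate_summits(peaks, genes_fwd),
               annotate_summits(peaks, genes_rev))
})

test_that("randomized peaks preserve lengths, avoid the blacklist, and are seeded", {
  si <- Seqinfo("chr1", 50000L)
  peaks <- GRanges("chr1", IRanges(c(1001, 20001), width = c(100, 250)),
                   seqinfo = si)
  bl <- GRanges("chr1", IRanges(c(5000, 30000), width = c(2000, 5000)))
  s1 <- randomize_peaks(peaks, bl, n_sets = 20, seed = 5)
  s2 <- randomize_peaks(peaks, bl, n_sets = 20, seed = 5)
  expect_identical(lapply(s1, ranges), lapply(s2, ranges))
  for (set in s1) {
    expect_equal(sort(width(set)), c(100L, 250L))
    expect_equal(sum(countOverlaps(set, bl)), 0L)
    expect_true(all(start(set) >= 1 & end(set) <= 50000))
  }
  s3 <- randomize_peaks(peaks, bl, n_sets = 20, seed = 6)
  expect_false(identical(lapply(s1, ranges), lapply(s3, ranges)))
})

test_that("a blacklist leaving one exactly-sized gap forces the placement", {
  si <- Seqinfo("chr1", 10000L)
  peak <- GRanges("chr1", IRanges(1, 100), seqinfo = si)
  bl <- GRanges("chr1", IRanges(c(1, 4101), c(4000, 10000)))
  sets <- randomize_peaks(peak, bl, n_sets = 5, seed = 1)
  for (set in sets) expect_equal(ranges(set), IRanges(4001, 4100))
  bl_tight <- GRanges("chr1", IRanges(c(1, 4051), c(4000, 10000)))
  expect_error(randomize_peaks(peak, bl_tight, n_sets = 1, seed = 1),
               "exceed the largest allowed gap")
})

test_that("random placement is uniform over allowed starts", {
  si <- Seqinfo("chr1", 10000L)
  # 10,000 independent placements of a 100-bp peak on a 10-kb chromosome
  peak <- GRanges("chr1", IRanges(rep(1, 10000), width = 100), seqinfo = si)
  starts <- start(randomize_peaks(peak, NULL, n_sets = 1, seed = 3)[[1]])
  expect_true(all(starts >= 1 & starts <= 9901))
  bins <- cut(starts, breaks = seq(0.5, 9901.5, length.out = 11))
  gof <- chisq.test(table(bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("the two-proportion z test matches hand values and the chi-square identity", {
  et0 <- enrichment_test(30, 100, 30, 100)
  expect_equal(et0$z, 0)
  expect_equal(et0$p.value, 1)

  et <- enrichment_test(30, 100, 10, 100)
  expect_equal(et$z, 3.536, tolerance = 1e-3)
  expect_equal(et$p.value, 4.06e-4, tolerance = 1e-2)
  chi <- chisq.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(et$z^2, unname(chi$statistic))
  expect_equal(et$ratio, 3)

  # swapping the arguments negates z
  et_sw <- enrichment_test(10, 100, 30, 100)
  expect_equal(et_sw$z, -et$z)
  expect_error(enrichment_test(5, 0, 1, 10), "positive")
  expect_error(enrichment_test(11, 10, 1, 10), "exceed")
})

test_that("peaks planted on ITRs show strong ITR enrichment vs the random null", {
  cfg <- simulation_config(seed = 31, n_offtarget = 5L,
                           expression = list(n_background_genes = 0L))
  loci <- generate_loci(cfg)
  chip <- generate_chip(loci)
  hits <- truth_hits(loci)
  enr <- peak_enrichment(chip$peaks, list(ITR = hits),
                         blacklist = loci$blacklist, n_sets = 20, seed = 8)
  expect_gt(enr$z[enr$category == "ITR"], 5)
  expect_lt(enr$p.value[enr$category == "ITR"], 1e-6)
  expect_gt(enr$ratio[enr$category == "ITR"], 1)
})

test_that("chromosome correlation reproduces hand-checked Spearman values", {
  lens <- c(chr1 = 4e6, chr2 = 3e6, chr3 = 2e6, chr4 = 1e6)
  mk <- function(counts) {
    GRanges(rep(names(lens), counts),
            IRanges(unlist(lapply(counts, seq_len)) * 1000, width = 19))
  }
  # perfectly monotone counts
  cc <- chromosome_correlation(mk(c(40, 30, 20, 10)), mk(c(8, 6, 4, 2)),
                               lens)
  expect_equal(cc$rho, c(1, 1, 1))
  # x=(1,2,3,4) vs y=(2,1,4,3): rho = 0.6
  cc2 <- chromosome_correlation(mk(c(1, 2, 3, 4)), mk(c(2, 1, 4, 3)),
                                lens)
  expect_equal(cc2$rho[cc2$comparison == "peaks_vs_itrs"], 0.6)
  expect_error(chromosome_correlation(mk(c(1, 1)), mk(c(1, 1)),
                                      lens[1:2]), "3 chromosomes")
})
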