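## ChIP peak analysis: interval extension, peak/ITR overlap, summit
## annotation against gene models, blacklist-aware randomized peak nulls,
## and the two-proportion enrichment test.

#' Extend intervals symmetrically, clipped at chromosome bounds
#'
#' @param intervals GRanges with seqlengths set for every chromosome in use.
#' @param flank Flank size in bp added on both sides (default 500).
#' @return GRanges grown by `flank` on each side and clipped to
#'   `[1, seqlength]`.
#' @export
extend_intervals <- function(intervals, flank = 500L) {
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) stop("flank must be >= 0")
  used <- unique(as.character(seqnames(intervals)))
  sl <- seqlengths(intervals)[used]
  if (length(used) && anyNA(sl))
    stop("unknown chromosome length for: ",
         paste(used[is.na(sl)], collapse = ", "))
  trim(suppressWarnings(intervals + flank))
}

#' Overlap ChIP peaks with ITR hits
#'
#' Peaks are extended by `flank` bp on both sides; overlap means at least
#' one shared base between an extended peak and a hit.
#'
#' @param peaks Peak GRanges.
#' @param hits ITR hit GRanges.
#' @param flank Peak extension in bp (default 500).
#' @return A list with `n_peaks`, `n_peaks_with_itr`, `frac_peaks_with_itr`,
#'   `n_itrs`, `n_itrs_in_peaks`, `frac_itrs_in_peaks`, and logical vectors
#'   `peak_has_itr`, `itr_in_peak`.
#' @export
overlap_peaks_itrs <- function(peaks, hits, flank = 500L) {
  ext <- extend_intervals(peaks, flank)
  peak_has_itr <- countOverlaps(ext, hits, ignore.strand = TRUE) > 0L
  itr_in_peak <- countOverlaps(hits, ext, ignore.strand = TRUE) > 0L
  list(
    n_peaks = length(peaks),
    n_peaks_with_itr = sum(peak_has_itr),
    frac_peaks_with_itr = if (length(peaks)) mean(peak_has_itr) else NA_real_,
    n_itrs = length(hits),
    n_itrs_in_peaks = sum(itr_in_peak),
    frac_itrs_in_peaks = if (length(hits)) mean(itr_in_peak) else NA_real_,
    peak_has_itr = peak_has_itr,
    itr_in_peak = itr_in_peak
  )
}

.summit_points <- function(peaks) {
  pos <- mcols(peaks)$summit
  if (is.null(pos)) pos <- (start(peaks) + end(peaks)) %/% 2L
  GRanges(seqnames(peaks), IRanges(pos, width = 1L),
          seqinfo = seqinfo(peaks))
}

#' Annotate peak summits with genomic categories
#'
#' Each summit receives exactly one category by fixed priority
#' TSS > TTS > exon > intron > intergenic. The TSS window is
#' `[tss - tss_up, tss + tss_down]` and the TTS window
#' `[tts - tts_up, tts + tts_down]`, both strand-aware.
#'
#' @param peaks Peak GRanges (uses the `summit` column when present, else
#'   interval midpoints).
#' @param genes A [gene_models()] object.
#' @param tss_up,tss_down TSS window, bp upstream/downstream (default
#'   1000/100).
#' @param tts_up,tts_down TTS window, bp upstream/downstream (default
#'   100/1000).
#' @return A factor of categories (levels TSS, TTS, exon, intron,
#'   intergenic), one per peak.
#' @export
annotate_summits <- function(peaks, genes, tss_up = 1000L, tss_down = 100L,
                             tts_up = 100L, tts_down = 1000L) {
  summits <- .summit_points(peaks)
  tssw <- .tss_windows(genes$genes, tss_up, tss_down)
  ttsw <- .tts_windows(genes$genes, tts_up, tts_down)
  exons <- unlist(genes$exons)
  span <- genes$genes
  cat_levels <- c("TSS", "TTS", "exon", "intron", "intergenic")
  out <- rep("intergenic", length(summits))
  hit <- function(feat) countOverlaps(summits, feat, ignore.strand = TRUE) > 0L
  in_span <- hit(span)
  out[in_span] <- "intron"
  out[hit(exons)] <- "exon"
  out[hit(ttsw)] <- "TTS"
  out[hit(tssw)] <- "TSS"
  factor(out, levels = cat_levels)
}

# Uniformly sample `n` start positions for intervals of width `len` within
# the allowed gaps (GRanges), without rejection: positions are drawn from the
# cumulative table of per-gap placements.
.sample_starts <- function(gaps, len, n) {
  avail <- width(gaps) - len + 1L
  keep <- avail > 0L
  if (!any(keep)) return(NULL)
  g_start <- start(gaps)[keep]
  cs <- cumsum(as.numeric(avail[keep]))
  total <- cs[length(cs)]
  u <- if (total <= .Machine$integer.max) {
    as.numeric(sample.int(as.integer(total), n, replace = TRUE))
  } else {
    floor(runif(n, 0, total)) + 1
  }
  gi <- findInterval(u - 0.5, c(0, cs))
  offset <- u - c(0, cs)[gi]
  as.integer(g_start[gi] + offset - 1)
}

#' Generate randomized peak sets excluding blacklisted regions
#'
#' Each randomized set preserves the per-chromosome peak count and the exact
#' multiset of peak lengths; placements are uniform over the allowed space
#' (chromosome minus blacklist) via a cumulative allowed-gap table, with no
#' rejection sampling. Random peaks may overlap each other, matching the
#' behaviour of standard interval shufflers.
#'
#' @param peaks Peak GRanges with seqlengths set.
#' @param blacklist GRanges of excluded regions, or NULL.
#' @param n_sets Number of randomized sets (default 100).
#' @param seed Integer seed; required for reproducibility.
#' @return A list of `n_sets` GRanges. The RNG kind used is recorded in the
#'   `"rng_kind"` attribute.
#' @export
randomize_peaks <- function(peaks, blacklist = NULL, n_sets = 100L,
                            seed = 1L) {
  used <- unique(as.character(seqnames(peaks)))
  sl <- seqlengths(peaks)[used]
  if (anyNA(sl))
    stop("peaks need seqlengths for: ", paste(used[is.na(sl)], collapse = ", "))
  full <- GRanges(used, IRanges(1L, unname(sl)))
  allowed <- if (is.null(blacklist) || length(blacklist) == 0L) full else
    setdiff(full, granges(blacklist), ignore.strand = TRUE)
  allowed_by_chrom <- split(allowed, seqnames(allowed))

  widths_by_chrom <- split(width(peaks), as.character(seqnames(peaks)))
  for (chrom in names(widths_by_chrom)) {
    gaps <- allowed_by_chrom[[chrom]]
    too_long <- widths_by_chrom[[chrom]] >
      if (length(gaps)) max(width(gaps)) else 0L
    if (any(too_long))
      stop("peak(s) of length ",
           paste(unique(widths_by_chrom[[chrom]][too_long]), collapse = ","),
           " bp on ", chrom, " exceed the largest allowed gap")
  }

  set.seed(as.integer(seed))
  si <- seqinfo(peaks)
  sets <- lapply(seq_len(n_sets), function(k) {
    chroms <- character(0); starts <- integer(0); ws_all <- integer(0)
    for (chrom in names(widths_by_chrom)) {
      ws <- widths_by_chrom[[chrom]]
      gaps <- allowed_by_chrom[[chrom]]
      st <- integer(length(ws))
      for (len in unique(ws)) {
        idx <- which(ws == len)
        st[idx] <- .sample_starts(gaps, len, length(idx))
      }
      chroms <- c(chroms, rep(chrom, length(ws)))
      starts <- c(starts, st)
      ws_all <- c(ws_all, ws)
    }
    GRanges(chroms, IRanges(starts, width = ws_all), seqinfo = si)
  })
  if (!is.null(blacklist) && length(blacklist)) {
    all_random <- unlist(as(sets, "GRangesList"))
    if (any(countOverlaps(all_random, blacklist, ignore.strand = TRUE) > 0L))
      stop("internal error: randomized peak overlaps blacklist")
  }
  attr(sets, "rng_kind") <- RNGkind()[1L]
  sets
}

#' Two-proportion enrichment z-test
#'
#' Pooled two-proportion z statistic comparing the observed hit proportion
#' with the proportion over randomized sets; `z^2` equals the 2x2 chi-square
#' statistic without continuity correction. The two-sided p-value uses the
#' normal approximation.
#'
#' @param observed_hits Number of observed intervals hitting the feature.
#' @param n_obs Total observed intervals.
#' @param random_hits Number of randomized intervals hitting the feature
#'   (pooled over sets).
#' @param n_rand Total randomized intervals (pooled).
#' @return A list with `observed`, `expected` (random proportion scaled to
#'   `n_obs`), `ratio` (observed/expected), `z`, and `p.value`.
#' @export
enrichment_test <- function(observed_hits, n_obs, random_hits, n_rand) {
  if (n_obs <= 0 || n_rand <= 0) stop("totals must be positive")
  if (observed_hits > n_obs || random_hits > n_rand)
    stop("hit counts cannot exceed totals")
  p1 <- observed_hits / n_obs
  p2 <- random_hits / n_rand
  pp <- (observed_hits + random_hits) / (n_obs + n_rand)
  se <- sqrt(pp * (1 - pp) * (1 / n_obs + 1 / n_rand))
  z <- if (se == 0) 0 else (p1 - p2) / se
  expected <- p2 * n_obs
  list(observed = observed_hits,
       expected = expected,
       ratio = if (expected > 0) observed_hits / expected else NA_real_,
       z = z,
       p.value = 2 * pnorm(-abs(z)))
}

#' Peak enrichment over feature categories against a randomized null
#'
#' For each feature set, counts observed peaks (extended by `flank`)
#' overlapping the feature, the same for every randomized peak set, and
#' applies [enrichment_test()] with the randomized counts pooled across
#' sets. Expected counts are the mean per randomized set. No
#' multiple-testing correction is applied; raw p-values are reported.
#'
#' @param peaks Peak GRanges with seqlengths.
#' @param features Named list (or GRangesList) of feature GRanges.
#' @param blacklist GRanges excluded from random placement, or NULL.
#' @param n_sets Number of randomized sets (default 100).
#' @param seed Integer seed for the randomization.
#' @param flank Peak extension in bp (default 500).
#' @return data.frame with one row per category: `category`, `observed`,
#'   `expected`, `ratio`, `z`, `p.value`.
#' @export
peak_enrichment <- function(peaks, features, blacklist = NULL,
                            n_sets = 100L, seed = 1L, flank = 500L) {
  sets <- randomize_peaks(peaks, blacklist = blacklist, n_sets = n_sets,
                          seed = seed)
  ext_obs <- extend_intervals(peaks, flank)
  ext_rand <- lapply(sets, extend_intervals, flank = flank)
  n_rand <- n_sets * length(peaks)
  rows <- lapply(names(features), function(cat) {
    feat <- features[[cat]]
    obs <- sum(countOverlaps(ext_obs, feat, ignore.strand = TRUE) > 0L)
    rnd <- sum(vapply(ext_rand, function(g)
      sum(countOverlaps(g, feat, ignore.strand = TRUE) > 0L), 0L))
    et <- enrichment_test(obs, length(peaks), rnd, n_rand)
    data.frame(category = cat, observed = obs, expected = rnd / n_sets,
               ratio = et$ratio, z = et$z, p.value = et$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-chromosome correlation of ITRs, peaks and chromosome length
#'
#' Spearman rank correlation (average ranks for ties) of per-chromosome ITR
#' counts vs chromosome length, peak counts vs length, and peak counts vs
#' ITR counts.
#'
#' @param hits ITR hit GRanges.
#' @param peaks Peak GRanges.
#' @param chrom_lengths Named vector of chromosome lengths (or a Seqinfo).
#' @return data.frame with columns `comparison`, `rho`, `p.value`.
#' @export
chromosome_correlation <- function(hits, peaks, chrom_lengths) {
  if (is(chrom_lengths, "Seqinfo"))
    chrom_lengths <- setNames(as.numeric(seqlengths(chrom_lengths)),
                              seqlevels(chrom_lengths))
  chroms <- names(chrom_lengths)
  if (length(chroms) < 3L) stop("need at least 3 chromosomes")
  itr_n <- as.numeric(table(factor(as.character(seqnames(hits)), chroms)))
  peak_n <- as.numeric(table(factor(as.character(seqnames(peaks)), chroms)))
  len <- as.numeric(chrom_lengths)
  one <- function(label, x, y) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(comparison = label, rho = unname(ct$estimate),
               p.value = ct$p.value, stringsAsFactors = FALSE)
  }
  rbind(one("itrs_vs_length", itr_n, len),
        one("peaks_vs_length", peak_n, len),
        one("peaks_vs_itrs", peak_n, itr_n))
}
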