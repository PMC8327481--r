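## Binding-affinity analysis: mean ChIP signal per ITR, stratification by
## mismatch group, the rank-sum test, and the single-substitution effect
## analysis over 1MM solo ITRs.

#' Length-weighted mean signal over intervals
#'
#' Mean per-base track value over each interval, counting uncovered bases as
#' zero.
#'
#' @param track [IRanges::RleList] signal track (see [signal_track()]).
#' @param intervals GRanges; every chromosome must exist in the track and
#'   widths must be positive.
#' @return Numeric vector of means, one per interval.
#' @export
mean_score_over_interval <- function(track, intervals) {
  if (length(intervals) == 0L) return(numeric(0))
  if (any(width(intervals) <= 0L)) stop("intervals must have positive width")
  chroms <- as.character(seqnames(intervals))
  missing <- setdiff(unique(chroms), names(track))
  if (length(missing))
    stop("track has no data for: ", paste(missing, collapse = ", "))
  out <- numeric(length(intervals))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    v <- Views(track[[chrom]], start(intervals)[idx], end(intervals)[idx])
    out[idx] <- viewMeans(v)
  }
  out
}

# Random motif-length background windows avoiding `exclude` (and blacklist).
.background_windows <- function(track, width, n, exclude = NULL,
                                blacklist = NULL) {
  sl <- vapply(track, length, 0L)
  full <- GRanges(names(track), IRanges(1L, unname(sl)))
  strip <- function(g) GRanges(seqnames(g), ranges(g))
  parts <- list()
  if (!is.null(exclude) && length(exclude))
    parts[[length(parts) + 1L]] <- strip(exclude)
  if (!is.null(blacklist) && length(blacklist))
    parts[[length(parts) + 1L]] <- strip(blacklist)
  allowed <- if (length(parts) == 0L) full else
    suppressWarnings(setdiff(full, reduce(do.call(c, parts)),
                             ignore.strand = TRUE))
  # weight chromosomes by allowed space, then place within
  by_chrom <- split(allowed, seqnames(allowed))
  avail <- vapply(by_chrom, function(g) sum(pmax(width(g) - width + 1L, 0L)),
                  0)
  si <- Seqinfo(seqnames = names(track), seqlengths = unname(sl))
  pick <- sample(names(by_chrom), n, replace = TRUE, prob = avail / sum(avail))
  counts <- table(pick)
  parts <- lapply(names(counts), function(chrom) {
    starts <- .sample_starts(by_chrom[[chrom]], width, counts[[chrom]])
    GRanges(chrom, IRanges(starts, width = width), seqinfo = si)
  })
  sort(do.call(c, parts))
}

#' Mean ChIP score per ITR, stratified by mismatch group
#'
#' Computes the mean track score over each hit, splits hits by mismatch
#' group, and adds a `"Total"` genomic-background group of `background_n`
#' random motif-length windows placed outside the hits (and outside the
#' blacklist when given).
#'
#' @param track [IRanges::RleList] signal track.
#' @param hits GRanges from [scan_motif()] with `mismatch_count`.
#' @param background_n Number of background windows (default 10000).
#' @param seed Integer seed for background placement.
#' @param blacklist Optional GRanges excluded from background placement.
#' @param max_mismatch Largest group label (default 3).
#' @return A list with `scores` (named list of numeric vectors, groups
#'   `"0MM"`..`"<k>MM"` and `"Total"`) and `summary` (data.frame `group`,
#'   `n`, `median`).
#' @export
scores_by_group <- function(track, hits, background_n = 10000L, seed = 1L,
                            blacklist = NULL, max_mismatch = 3L) {
  s <- mean_score_over_interval(track, hits)
  groups <- paste0(mcols(hits)$mismatch_count, "MM")
  lev <- paste0(0:max_mismatch, "MM")
  scores <- lapply(lev, function(g) unname(s[groups == g]))
  names(scores) <- lev
  set.seed(as.integer(seed))
  wid <- if (length(hits)) width(hits)[1L] else 19L
  bg <- .background_windows(track, wid, background_n, exclude = hits,
                            blacklist = blacklist)
  scores$Total <- mean_score_over_interval(track, bg)
  summary <- data.frame(
    group = names(scores),
    n = vapply(scores, length, 0L),
    median = vapply(scores, function(x)
      if (length(x)) median(x) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(scores = scores, summary = summary)
}

#' Wilcoxon rank-sum test with an exact small-sample branch
#'
#' For combined sample sizes up to `exact_limit` the two-sided p-value is
#' computed by full enumeration of all rank assignments (a permutation test
#' on the rank-sum statistic, valid with ties via average ranks). Larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_limit Largest combined size for exact enumeration
#'   (default 12).
#' @return A list with `statistic` (rank sum of `x`), `p.value`, and
#'   `method`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 12L) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  if (N <= exact_limit) {
    combs <- combn(N, m)
    Wall <- colSums(matrix(r[combs], nrow = m))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    list(statistic = W, p.value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = W, p.value = wt$p.value,
         method = "normal approximation")
  }
}

#' Single-substitution effects on binding affinity
#'
#' Groups 1MM solo ITRs by their substitution (motif position, motif base,
#' observed base), drops groups rarer than `min_frequency` percent of all
#' 1MM solos (strict inequality), and compares each remaining group's mean
#' ChIP scores against the 0MM solo reference with [rank_sum_test()].
#' Fold change is the ratio of medians (0MM solo median / group median).
#'
#' @param track [IRanges::RleList] signal track.
#' @param elements GRanges from [pair_itrs()].
#' @param min_frequency Frequency cutoff in percent (default 2).
#' @return data.frame with columns `position`, `from`, `to`, `n`,
#'   `frequency` (percent of 1MM solos), `median_score`, `fold_change`,
#'   `p.value`, sorted by position then bases. The pre-filter frequency
#'   total is available as attribute `"total_frequency"`.
#' @export
substitution_effects <- function(track, elements, min_frequency = 2) {
  solo <- elements[mcols(elements)$kind == "solo"]
  ref <- solo[mcols(solo)$mm1 == 0L]
  if (length(ref) == 0L) stop("no 0MM solo ITRs to use as reference")
  mm1 <- solo[mcols(solo)$mm1 == 1L]
  ref_scores <- mean_score_over_interval(track, ref)
  ref_median <- median(ref_scores)
  if (length(mm1) == 0L)
    return(structure(data.frame(position = integer(0), from = character(0),
                                to = character(0), n = integer(0),
                                frequency = numeric(0),
                                median_score = numeric(0),
                                fold_change = numeric(0),
                                p.value = numeric(0)),
                     total_frequency = NA_real_))
  prof <- lapply(mcols(mm1)$profile1, parse_profile)
  if (any(vapply(prof, nrow, 0L) != 1L))
    stop("every 1MM solo must carry exactly one profile entry")
  key <- data.frame(
    position = vapply(prof, function(p) p$position, 0L),
    from = vapply(prof, function(p) p$motif_base, ""),
    to = vapply(prof, function(p) p$observed_base, ""))
  scores <- mean_score_over_interval(track, mm1)
  total <- length(mm1)
  grp <- interaction(key$position, key$from, key$to, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    k <- key[idx[1L], ]
    gs <- scores[idx]
    gm <- median(gs)
    data.frame(position = k$position, from = k$from, to = k$to,
               n = length(idx), frequency = 100 * length(idx) / total,
               median_score = gm,
               fold_change = ref_median / gm,
               p.value = rank_sum_test(gs, ref_scores)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total_freq <- sum(out$frequency)
  out <- out[out$frequency >= min_frequency, , drop = FALSE]
  out <- out[order(out$position, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_frequency") <- total_freq
  out
}
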