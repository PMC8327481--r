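## Expression analysis: associate genes with ITRs over TSS-exon-intron-TTS
## spans, stratify genes by best (minimum) ITR mismatch, and compare FPKM
## distributions against a random gene group.

#' Associate genes with ITR hits or peak summits
#'
#' A gene is associated when at least one ITR hit (default) or peak summit
#' falls within the union of its TSS window, exons, introns and TTS window;
#' its group is the minimum mismatch count among associated ITRs. When
#' associating by summits, the group is the minimum mismatch of hits
#' overlapping the extended associated peaks; peaks must then be provided
#' via `peaks`.
#'
#' @param hits ITR hit GRanges with `mismatch_count`.
#' @param genes A [gene_models()] object.
#' @param mode `"hits"` (default): associate by ITR hit position;
#'   `"summits"`: associate by peak summit position.
#' @param peaks Peak GRanges, required for `mode = "summits"`.
#' @param tss_up,tss_down,tts_up,tts_down Window sizes in bp, as in
#'   [annotate_summits()].
#' @return data.frame with columns `gene_id`, `group` (integer minimum
#'   mismatch) and `label` (`"MM<k>"`).
#' @export
associate_genes <- function(hits, genes, mode = c("hits", "summits"),
                            peaks = NULL, tss_up = 1000L, tss_down = 100L,
                            tts_up = 100L, tts_down = 1000L) {
  mode <- match.arg(mode)
  region <- punion(
    punion(genes$genes, .tss_windows(genes$genes, tss_up, tss_down),
           fill.gap = TRUE),
    .tts_windows(genes$genes, tts_up, tts_down), fill.gap = TRUE)
  if (mode == "hits") {
    ov <- findOverlaps(region, hits, ignore.strand = TRUE)
    mm <- mcols(hits)$mismatch_count[subjectHits(ov)]
  } else {
    if (is.null(peaks)) stop("mode 'summits' needs peaks")
    summits <- .summit_points(peaks)
    ov_p <- findOverlaps(region, summits, ignore.strand = TRUE)
    ext <- extend_intervals(peaks, 500L)
    ov_h <- findOverlaps(ext, hits, ignore.strand = TRUE)
    mm_by_peak <- tapply(mcols(hits)$mismatch_count[subjectHits(ov_h)],
                         queryHits(ov_h), min)
    mm <- unname(mm_by_peak[as.character(subjectHits(ov_p))])
    keep <- !is.na(mm)
    ov <- ov_p[keep]
    mm <- mm[keep]
  }
  if (length(ov) == 0L)
    return(data.frame(gene_id = character(0), group = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  best <- tapply(mm, queryHits(ov), min)
  gene_id <- mcols(genes$genes)$gene_id[as.integer(names(best))]
  data.frame(gene_id = gene_id, group = as.integer(best),
             label = paste0("MM", as.integer(best)),
             stringsAsFactors = FALSE)
}

#' Compare FPKM distributions by ITR-fidelity group against random genes
#'
#' Draws a seeded random gene group from non-associated genes (optionally
#' restricted to expressed genes), then runs a two-sided rank-sum test of
#' each MM group against it. Genes with multiple expression records keep
#' their maximum FPKM; associated genes missing from the expression table
#' are dropped with their count reported.
#'
#' @param assoc data.frame from [associate_genes()].
#' @param expression data.frame with `gene_id`, `fpkm`.
#' @param random_n Size of the random group; default: total associated
#'   genes with expression.
#' @param seed Integer seed for the random draw.
#' @param universe `"all"`: sample among all non-associated genes in the
#'   expression table; `"expressed"`: only those with FPKM > 0.
#' @return A list with `groups` (named list of FPKM vectors, MM groups plus
#'   `"random"`), `tests` (data.frame `group`, `n`, `median`, `p_vs_random`),
#'   `n_missing_expression` and `random_gene_ids`.
#' @export
expression_compare <- function(assoc, expression, random_n = NULL,
                               seed = 1L, universe = c("all", "expressed")) {
  universe <- match.arg(universe)
  fpkm <- tapply(expression$fpkm, expression$gene_id, max)
  have <- assoc$gene_id %in% names(fpkm)
  n_missing <- sum(!have)
  assoc <- assoc[have, , drop = FALSE]
  if (!any(assoc$group == 0L)) stop("empty MM0 group")
  pool_ids <- setdiff(names(fpkm), assoc$gene_id)
  if (universe == "expressed")
    pool_ids <- pool_ids[fpkm[pool_ids] > 0]
  if (is.null(random_n)) random_n <- nrow(assoc)
  if (random_n > length(pool_ids))
    stop("not enough non-associated genes for the random group")
  set.seed(as.integer(seed))
  random_ids <- sample(pool_ids, random_n)
  rand <- unname(fpkm[random_ids])
  labels <- sort(unique(assoc$label))
  groups <- lapply(labels, function(l)
    unname(fpkm[assoc$gene_id[assoc$label == l]]))
  names(groups) <- labels
  tests <- do.call(rbind, lapply(labels, function(l) {
    g <- groups[[l]]
    data.frame(group = l, n = length(g), median = median(g),
               p_vs_random = rank_sum_test(g, rand)$p.value,
               stringsAsFactors = FALSE)
  }))
  tests <- rbind(tests,
                 data.frame(group = "random", n = length(rand),
                            median = median(rand), p_vs_random = NA_real_,
                            stringsAsFactors = FALSE))
  groups$random <- rand
  list(groups = groups, tests = tests, n_missing_expression = n_missing,
       random_gene_ids = random_ids)
}
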