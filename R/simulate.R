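## Synthetic-data generator: genomes with planted ITR loci at controlled
## mismatch counts, MITE-like inverted pairs, blacklists, fidelity-biased
## ChIP peaks and signal, and fidelity-shifted expression tables — all with
## a hit-level truth table so every pipeline stage is testable offline.

.child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream * 7919) %% 2147483562)
}

#' Configure a synthetic study
#'
#' Defaults define the standard simulated study: four 280-kb chromosomes
#' carrying 100 isolated ITR loci with fixed per-group counts (20/30/25/25
#' for 0-3 mismatches), 200 MITE-like inverted pairs with inner gaps of
#' 20-40 bp (median element length about 68 bp), 300 further solo ITRs with
#' uniform groups, a ~5% blacklist, ChIP peaks placed on a per-group
#' fraction of ITRs (80/50/20/10% for 0-3MM), a piecewise-constant signal of
#' amplitude `S0 * decay^mismatches` times per-position substitution
#' multipliers (strongest loss at motif position 17) over peaked loci plus
#' Gaussian noise, and log-normal FPKM values shifted down for genes
#' harbouring high-fidelity ITRs. A separate motif-free chromosome carries
#' the non-associated background genes.
#'
#' @param seed Master integer seed; per-artifact child seeds are derived
#'   from it deterministically.
#' @param n_chrom,chrom_length Number of element-bearing chromosomes and
#'   their lengths (recycled to `n_chrom`); defaults vary so per-chromosome
#'   element counts covary with chromosome length.
#' @param planted_groups Named or ordered counts of isolated loci for
#'   mismatch groups 0..3.
#' @param n_mite Number of planted inverted pairs.
#' @param mite_gap Inner-gap range (bp), drawn uniformly.
#' @param n_solo Number of extra solo loci with uniform random groups.
#' @param element_spacing Range of gaps between consecutive planted elements
#'   (bp); the minimum must exceed the 500-bp pairing window so planted
#'   solos stay solo.
#' @param blacklist_fraction Approximate fraction of the genome blacklisted.
#' @param substitution_spectrum data.frame (`position`, `to`, `weight`) of
#'   favoured substitutions; remaining probability is spread uniformly over
#'   all other (position, base) combinations.
#' @param peak_fraction Per-group probability (groups 0..3) that an ITR
#'   locus receives a ChIP peak.
#' @param n_offtarget Number of off-target peaks placed away from ITRs.
#' @param signal List: `S0` (base amplitude), `decay` (per-mismatch factor
#'   in (0,1]), `sigma` (Gaussian noise sd), `halfwidth` (peak half-width,
#'   bp), `position_effects` (named multipliers per substituted motif
#'   position, or NULL).
#' @param expression List: `n_itr_genes` genes placed over planted elements,
#'   `n_background_genes` genes on the motif-free chromosome, log-normal
#'   `mu`/`sigma`, and per-group log-mean `shift` (groups 0..3).
#' @param motif,max_mismatch Motif scanned for, and the mismatch ceiling.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chrom = 4L,
    chrom_length = c(360000L, 320000L, 280000L, 240000L),
    planted_groups = c(`0` = 20L, `1` = 30L, `2` = 25L, `3` = 25L),
    n_mite = 200L,
    mite_gap = c(20L, 40L),
    n_solo = 300L,
    element_spacing = c(1250L, 1600L),
    blacklist_fraction = 0.05,
    substitution_spectrum = data.frame(
      position = c(17L, 17L, 18L, 18L, 2L, 4L),
      to = c("T", "A", "A", "T", "A", "A"),
      weight = c(0.18, 0.15, 0.20, 0.18, 0.02, 0.02)),
    peak_fraction = c(`0` = 0.8, `1` = 0.5, `2` = 0.2, `3` = 0.1),
    n_offtarget = 5L,
    signal = list(),
    expression = list(),
    motif = ITR_CORE_MOTIF,
    max_mismatch = 3L) {
  signal <- utils::modifyList(
    list(S0 = 100, decay = 0.5, sigma = 5, halfwidth = 150L,
         position_effects = c(`2` = 0.3, `4` = 0.3, `14` = 0.5,
                              `17` = 0.22, `18` = 0.75, `19` = 0.5)),
    signal)
  expression <- utils::modifyList(
    list(n_itr_genes = 150L, n_background_genes = 300L, mu = 2, sigma = 1,
         shift = c(`0` = -1, `1` = -0.5, `2` = -0.25, `3` = 0)),
    expression)
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = rep_len(as.integer(chrom_length),
                                     as.integer(n_chrom)),
              planted_groups = as.integer(planted_groups),
              n_mite = as.integer(n_mite),
              mite_gap = as.integer(mite_gap),
              n_solo = as.integer(n_solo),
              element_spacing = as.integer(element_spacing),
              blacklist_fraction = blacklist_fraction,
              substitution_spectrum = substitution_spectrum,
              peak_fraction = as.numeric(peak_fraction),
              n_offtarget = as.integer(n_offtarget),
              signal = signal, expression = expression,
              motif = motif, max_mismatch = as.integer(max_mismatch))
  stopifnot(length(cfg$planted_groups) == cfg$max_mismatch + 1L,
            all(cfg$planted_groups >= 0L), cfg$n_mite >= 0L,
            cfg$n_solo >= 0L,
            cfg$signal$decay > 0, cfg$signal$decay <= 1,
            cfg$signal$sigma >= 0,
            all(cfg$peak_fraction >= 0), all(cfg$peak_fraction <= 1),
            cfg$blacklist_fraction >= 0, cfg$blacklist_fraction < 1)
  if (cfg$element_spacing[1L] <= 500L + nchar(cfg$motif))
    stop("element_spacing must exceed the 500-bp pairing window")
  if (sum(cfg$substitution_spectrum$weight) > 1)
    stop("substitution_spectrum weights must sum to at most 1")
  class(cfg) <- "sim_config"
  cfg
}

# Full (position, to) substitution table with per-combination weights.
.substitution_table <- function(motif, spectrum) {
  mchars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  tab <- do.call(rbind, lapply(seq_along(mchars), function(p)
    data.frame(position = p, from = mchars[p],
               to = setdiff(bases, mchars[p]), stringsAsFactors = FALSE)))
  tab$weight <- 0
  named <- 0
  if (!is.null(spectrum) && nrow(spectrum)) {
    key <- paste(tab$position, tab$to)
    skey <- paste(spectrum$position, spectrum$to)
    if (!all(skey %in% key))
      stop("substitution_spectrum refers to invalid positions/bases")
    tab$weight[match(skey, key)] <- spectrum$weight
    named <- sum(spectrum$weight)
  }
  rest <- tab$weight == 0
  tab$weight[rest] <- (1 - named) / sum(rest)
  tab
}

# Draw k substitutions at distinct positions from the weighted table;
# returns list(seq = mutated motif string, profile = profile string).
.mutate_motif <- function(mchars, k, tab) {
  if (k == 0L)
    return(list(seq = paste(mchars, collapse = ""), profile = ""))
  chosen <- integer(0)
  while (length(chosen) < k) {
    i <- sample.int(nrow(tab), 1L, prob = tab$weight)
    if (!(tab$position[i] %in% tab$position[chosen]))
      chosen <- c(chosen, i)
  }
  chosen <- chosen[order(tab$position[chosen])]
  out <- mchars
  out[tab$position[chosen]] <- tab$to[chosen]
  prof <- paste0(tab$position[chosen], ":", tab$from[chosen], ">",
                 tab$to[chosen], collapse = ",")
  list(seq = paste(out, collapse = ""), profile = prof)
}

#' Place planted loci and build the truth table (no sequence)
#'
#' The positional layer of the simulation: element placement, mismatch
#' profiles, strands and the blacklist, without generating sequence. Used
#' directly for statistical simulations where only locus geometry matters;
#' [generate_genome()] adds the sequence and the scanner-verified background.
#'
#' @param config A [simulation_config()].
#' @return A list of class `itr_loci`: `truth` (one row per planted ITR hit:
#'   chrom, start, end, strand, mm, profile, matched_seq, element_id, kind,
#'   role, origin), `elements` (designed element table), `seqinfo`,
#'   `blacklist`, `config`.
#' @export
generate_loci <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 1L))
  w <- nchar(config$motif)
  mchars <- strsplit(config$motif, "", fixed = TRUE)[[1L]]
  tab <- .substitution_table(config$motif, config$substitution_spectrum)

  groups_fixed <- rep(seq_along(config$planted_groups) - 1L,
                      config$planted_groups)
  el <- rbind(
    if (length(groups_fixed))
      data.frame(kind = "solo", mm1 = groups_fixed, mm2 = NA_integer_),
    if (config$n_solo > 0L)
      data.frame(kind = "solo",
                 mm1 = sample(0:config$max_mismatch, config$n_solo, TRUE),
                 mm2 = NA_integer_),
    if (config$n_mite > 0L)
      data.frame(kind = "MITE",
                 mm1 = sample(0:config$max_mismatch, config$n_mite, TRUE),
                 mm2 = sample(0:config$max_mismatch, config$n_mite, TRUE)))
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqlen <- setNames(config$chrom_length, chroms)
  if (config$expression$n_background_genes > 0L)
    seqlen <- c(seqlen,
                chrBG = config$expression$n_background_genes * 1400L + 20000L)

  truth <- NULL
  elements <- NULL
  if (!is.null(el) && nrow(el)) {
    el <- el[sample.int(nrow(el)), , drop = FALSE]
    el$element_id <- sprintf("el_%04d", seq_len(nrow(el)))
    # element density scales with chromosome length, as in real genomes
    el$chrom <- sample(chroms, nrow(el), replace = TRUE,
                       prob = seqlen[chroms])
    rows <- vector("list", nrow(el))
    cursor <- setNames(rep(1000L, config$n_chrom), chroms)
    for (i in seq_len(nrow(el))) {
      chrom <- el$chrom[i]
      gap <- sample(config$element_spacing[1L]:config$element_spacing[2L], 1L)
      s1 <- cursor[[chrom]] + gap
      v1 <- .mutate_motif(mchars, el$mm1[i], tab)
      if (el$kind[i] == "MITE") {
        inner <- sample(config$mite_gap[1L]:config$mite_gap[2L], 1L)
        s2 <- s1 + w + inner
        v2 <- .mutate_motif(mchars, el$mm2[i], tab)
        end2 <- s2 + w - 1L
        rows[[i]] <- data.frame(
          chrom = chrom, start = c(s1, s2), end = c(s1 + w - 1L, end2),
          strand = c("+", "-"), mm = c(el$mm1[i], el$mm2[i]),
          profile = c(v1$profile, v2$profile),
          matched_seq = c(v1$seq, v2$seq),
          element_id = el$element_id[i], kind = "MITE",
          role = c("mite1", "mite2"), origin = "planted",
          stringsAsFactors = FALSE)
        cursor[[chrom]] <- end2
      } else {
        rows[[i]] <- data.frame(
          chrom = chrom, start = s1, end = s1 + w - 1L,
          strand = sample(c("+", "-"), 1L), mm = el$mm1[i],
          profile = v1$profile, matched_seq = v1$seq,
          element_id = el$element_id[i], kind = "solo",
          role = "solo", origin = "planted", stringsAsFactors = FALSE)
        cursor[[chrom]] <- s1 + w - 1L
      }
      if (cursor[[chrom]] > seqlen[[chrom]] - 1000L)
        stop("infeasible packing: elements exceed chromosome length on ",
             chrom)
    }
    truth <- do.call(rbind, rows)
    el_start <- tapply(truth$start, truth$element_id, min)
    el_end <- tapply(truth$end, truth$element_id, max)
    elements <- el[c("element_id", "chrom", "kind", "mm1", "mm2")]
    elements$start <- as.integer(el_start[elements$element_id])
    elements$end <- as.integer(el_end[elements$element_id])
    elements$mm_min <- pmin(elements$mm1, elements$mm2, na.rm = TRUE)
  } else {
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        mm = integer(0), profile = character(0),
                        matched_seq = character(0),
                        element_id = character(0), kind = character(0),
                        role = character(0), origin = character(0),
                        stringsAsFactors = FALSE)
    elements <- data.frame(element_id = character(0), chrom = character(0),
                           kind = character(0), mm1 = integer(0),
                           mm2 = integer(0), start = integer(0),
                           end = integer(0), mm_min = integer(0),
                           stringsAsFactors = FALSE)
  }

  si <- Seqinfo(seqnames = names(seqlen), seqlengths = unname(seqlen))
  blacklist <- .place_blacklist(truth, si, config)
  structure(list(truth = truth, elements = elements, seqinfo = si,
                 blacklist = blacklist, config = config),
            class = "itr_loci")
}

# Blacklist intervals in inter-element space, >= 300 bp from planted loci.
.place_blacklist <- function(truth, si, config) {
  if (config$blacklist_fraction <= 0)
    return(GRanges(seqinfo = si))
  target <- config$blacklist_fraction * sum(as.numeric(seqlengths(si)))
  full <- GRanges(seqlevels(si), IRanges(1L, unname(seqlengths(si))),
                  seqinfo = si)
  occupied <- if (nrow(truth))
    GRanges(truth$chrom, IRanges(truth$start - 300L, truth$end + 300L))
  else GRanges()
  free <- if (length(occupied))
    suppressWarnings(setdiff(full, occupied, ignore.strand = TRUE)) else full
  free <- free[width(free) >= 700L]
  free <- free[sample.int(length(free))]
  picked <- GRanges(seqinfo = si)
  total <- 0
  for (i in seq_along(free)) {
    if (total >= target) break
    wdt <- min(500L, width(free)[i] - 200L)
    off <- sample.int(width(free)[i] - wdt + 1L, 1L)
    iv <- GRanges(seqnames(free)[i],
                  IRanges(start(free)[i] + off - 1L, width = wdt),
                  seqinfo = si)
    picked <- c(picked, iv)
    total <- total + wdt
  }
  sort(picked)
}

#' Convert a truth table to a hit GRanges
#'
#' @param x An `itr_loci` / `itr_sim` object, or a truth data.frame.
#' @return GRanges with the same metadata as [scan_motif()] output plus
#'   `element_id`, `kind`, `role`, `origin`.
#' @export
truth_hits <- function(x) {
  truth <- if (is.data.frame(x)) x else x$truth
  si <- if (is.data.frame(x)) NULL else x$seqinfo
  gr <- GRanges(truth$chrom, IRanges(truth$start, truth$end),
                strand = truth$strand,
                mismatch_count = truth$mm, matched_seq = truth$matched_seq,
                profile = truth$profile, element_id = truth$element_id,
                kind = truth$kind, role = truth$role, origin = truth$origin)
  if (!is.null(si)) {
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
  }
  sort(gr, ignore.strand = TRUE)
}

#' Generate a synthetic genome with planted ITR loci
#'
#' Embeds the planted loci of [generate_loci()] in uniform-random A/C/G/T
#' background (minus-strand loci are inserted as reverse complements), scans
#' the result, verifies that every planted locus is recovered with its
#' designed mismatch count, and appends any accidental background matches to
#' the truth table with `origin = "background"`.
#'
#' @param config A [simulation_config()].
#' @param loci Optionally a pre-built [generate_loci()] result.
#' @return A list of class `itr_sim`: everything in `itr_loci` plus
#'   `genome` (named character vector of chromosome sequences).
#' @export
generate_genome <- function(config = simulation_config(), loci = NULL) {
  if (is.null(loci)) loci <- generate_loci(config)
  config <- loci$config
  set.seed(.child_seed(config$seed, 2L))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seqlevels(loci$seqinfo), function(chrom) {
    L <- seqlengths(loci$seqinfo)[[chrom]]
    chars <- sample(bases, L, replace = TRUE)
    rows <- loci$truth[loci$truth$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      insert <- if (rows$strand[i] == "+") rows$matched_seq[i] else
        revcomp(rows$matched_seq[i])
      chars[rows$start[i]:rows$end[i]] <-
        strsplit(insert, "", fixed = TRUE)[[1L]]
    }
    paste(chars, collapse = "")
  }, "")

  hits <- scan_motif(seqs, motif_spec(config$motif, config$max_mismatch))
  key <- function(chrom, start, strand) paste(chrom, start, strand)
  hit_key <- key(as.character(seqnames(hits)), start(hits),
                 as.character(strand(hits)))
  truth_key <- key(loci$truth$chrom, loci$truth$start, loci$truth$strand)
  found <- match(truth_key, hit_key)
  if (anyNA(found))
    stop("infeasible packing: ", sum(is.na(found)),
         " planted locus/loci not recovered by the scanner")
  if (!all(mcols(hits)$mismatch_count[found] == loci$truth$mm))
    stop("planted locus recovered with unexpected mismatch count")
  extra <- setdiff(seq_along(hits), found)
  if (length(extra)) {
    bg <- data.frame(
      chrom = as.character(seqnames(hits))[extra],
      start = start(hits)[extra], end = end(hits)[extra],
      strand = as.character(strand(hits))[extra],
      mm = mcols(hits)$mismatch_count[extra],
      profile = mcols(hits)$profile[extra],
      matched_seq = mcols(hits)$matched_seq[extra],
      element_id = NA_character_, kind = "solo", role = "solo",
      origin = "background", stringsAsFactors = FALSE)
    loci$truth <- rbind(loci$truth, bg)
    o <- order(loci$truth$chrom, loci$truth$start)
    loci$truth <- loci$truth[o, , drop = FALSE]
    rownames(loci$truth) <- NULL
  }
  loci$genome <- seqs
  class(loci) <- c("itr_sim", "itr_loci")
  loci
}

#' Generate synthetic ChIP peaks and signal
#'
#' Assigns each truth locus a peak with its group's probability, builds the
#' per-base signal (amplitude `S0 * decay^mm` times per-position
#' substitution multipliers over peaked loci +/- `halfwidth`, Gaussian noise
#' everywhere on top), and places `n_offtarget` peaks of amplitude `S0` away
#' from any ITR.
#'
#' @param loci An `itr_loci` or `itr_sim` object.
#' @param config Optional [simulation_config()] overriding `loci$config`.
#' @return A list with `peaks` (GRanges: name, score, summit, signalValue),
#'   `track` ([IRanges::RleList]), and `truth` (loci truth with a `peaked`
#'   column).
#' @export
generate_chip <- function(loci, config = NULL) {
  if (is.null(config)) config <- loci$config
  set.seed(.child_seed(config$seed, 3L))
  truth <- loci$truth
  sg <- config$signal
  hw <- as.integer(sg$halfwidth)
  sl <- seqlengths(loci$seqinfo)

  amp_of <- function(mm, profile) {
    a <- sg$S0 * sg$decay^mm
    if (!is.null(sg$position_effects) && nzchar(profile)) {
      pos <- as.character(parse_profile(profile)$position)
      eff <- sg$position_effects[pos]
      a <- a * prod(eff[!is.na(eff)])
    }
    a
  }
  n <- nrow(truth)
  truth$peaked <- if (n) runif(n) < config$peak_fraction[truth$mm + 1L]
    else logical(0)
  truth$amplitude <- if (n) mapply(amp_of, truth$mm, truth$profile)
    else numeric(0)

  tracks <- lapply(seqlevels(loci$seqinfo), function(chrom) {
    L <- sl[[chrom]]
    v <- if (sg$sigma > 0) rnorm(L, 0, sg$sigma) else numeric(L)
    rows <- truth[truth$chrom == chrom & truth$peaked, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      a <- max(rows$start[i] - hw, 1L)
      b <- min(rows$end[i] + hw, L)
      v[a:b] <- v[a:b] + rows$amplitude[i]
    }
    Rle(v)
  })
  names(tracks) <- seqlevels(loci$seqinfo)

  pk_rows <- truth[truth$peaked, , drop = FALSE]
  peaks <- GRanges(seqinfo = loci$seqinfo)
  if (nrow(pk_rows)) {
    peaks <- GRanges(
      pk_rows$chrom,
      IRanges(pmax(pk_rows$start - hw, 1L),
              pmin(pk_rows$end + hw, sl[pk_rows$chrom])),
      seqinfo = loci$seqinfo)
    mcols(peaks)$summit <- (pk_rows$start + pk_rows$end) %/% 2L
    mcols(peaks)$score <- pk_rows$amplitude
  }
  if (config$n_offtarget > 0L) {
    full <- GRanges(seqlevels(loci$seqinfo), IRanges(1L, unname(sl)),
                    seqinfo = loci$seqinfo)
    margin <- 500L + hw + 50L
    occupied <- if (n)
      GRanges(truth$chrom, IRanges(pmax(truth$start - margin, 1L),
                                   truth$end + margin)) else GRanges()
    bl <- GRanges(seqnames(loci$blacklist), ranges(loci$blacklist))
    drop <- reduce(suppressWarnings(c(occupied, bl)))
    allowed <- if (length(drop))
      suppressWarnings(setdiff(full, drop, ignore.strand = TRUE)) else full
    wdt <- 2L * hw + nchar(config$motif)
    by_chrom <- split(allowed, seqnames(allowed))
    avail <- vapply(by_chrom, function(g)
      sum(pmax(width(g) - wdt + 1L, 0L)), 0)
    pick <- sample(names(by_chrom), config$n_offtarget, replace = TRUE,
                   prob = avail / sum(avail))
    counts <- table(pick)
    offs <- do.call(c, lapply(names(counts), function(chrom) {
      starts <- .sample_starts(by_chrom[[chrom]], wdt, counts[[chrom]])
      GRanges(chrom, IRanges(starts, width = wdt), seqinfo = loci$seqinfo)
    }))
    mcols(offs)$summit <- (start(offs) + end(offs)) %/% 2L
    mcols(offs)$score <- sg$S0
    for (i in seq_along(offs)) {
      chrom <- as.character(seqnames(offs))[i]
      idx <- start(offs)[i]:end(offs)[i]
      v <- as.numeric(tracks[[chrom]][idx]) + sg$S0
      tracks[[chrom]][idx] <- v
    }
    peaks <- c(peaks, offs)
  }
  peaks <- sort(peaks)
  if (length(peaks))
    mcols(peaks)$name <- paste0("peak_", seq_along(peaks))
  mcols(peaks)$signalValue <- mcols(peaks)$score
  list(peaks = peaks, track = as(tracks, "RleList"), truth = truth)
}

#' Generate synthetic gene models and expression
#'
#' Places genes over a sample of planted elements (the ITR sits in the
#' intron between two flanking exons) and background genes on the motif-free
#' chromosome, then draws FPKM from a log-normal whose log-mean is shifted
#' by the gene's element group (minimum mismatch).
#'
#' @param loci An `itr_loci` or `itr_sim` object.
#' @param config Optional [simulation_config()] overriding `loci$config`.
#' @return A list with `genes` ([gene_models()]), `fpkm` (data.frame
#'   `gene_id`, `fpkm`) and `truth` (data.frame `gene_id`, `group`,
#'   `label`; background genes have group NA / label "none").
#' @export
generate_expression <- function(loci, config = NULL) {
  if (is.null(config)) config <- loci$config
  set.seed(.child_seed(config$seed, 4L))
  ex_cfg <- config$expression
  el <- loci$elements
  n_itr <- min(ex_cfg$n_itr_genes, nrow(el))
  chosen <- if (n_itr > 0L) el[sample.int(nrow(el), n_itr), , drop = FALSE]
    else el[0, , drop = FALSE]

  exon_rows <- list()
  truth_rows <- list()
  if (n_itr > 0L) {
    gid <- sprintf("gene_itr_%03d", seq_len(n_itr))
    gstart <- chosen$start - 150L
    gend <- chosen$end + 150L
    exon_rows$itr <- GRanges(
      rep(chosen$chrom, each = 2L),
      IRanges(as.vector(rbind(gstart, gend - 60L)),
              as.vector(rbind(gstart + 60L, gend))),
      strand = "+", gene_id = rep(gid, each = 2L))
    truth_rows$itr <- data.frame(
      gene_id = gid, group = chosen$mm_min,
      label = paste0("MM", chosen$mm_min), stringsAsFactors = FALSE)
  }
  n_bg <- ex_cfg$n_background_genes
  if (n_bg > 0L) {
    gid <- sprintf("gene_bg_%03d", seq_len(n_bg))
    gstart <- 10000L + (seq_len(n_bg) - 1L) * 1400L
    gend <- gstart + 400L
    exon_rows$bg <- GRanges(
      "chrBG",
      IRanges(as.vector(rbind(gstart, gend - 60L)),
              as.vector(rbind(gstart + 60L, gend))),
      strand = "+", gene_id = rep(gid, each = 2L))
    truth_rows$bg <- data.frame(gene_id = gid, group = NA_integer_,
                                label = "none", stringsAsFactors = FALSE)
  }
  if (length(exon_rows) == 0L) stop("no genes to generate")
  exons <- suppressWarnings(do.call(c, unname(exon_rows)))
  seqlevels(exons) <- seqlevels(loci$seqinfo)
  seqinfo(exons) <- loci$seqinfo
  truth <- do.call(rbind, unname(truth_rows))

  shift <- ifelse(is.na(truth$group), 0, ex_cfg$shift[truth$group + 1L])
  fpkm <- rlnorm(nrow(truth), meanlog = ex_cfg$mu + shift,
                 sdlog = ex_cfg$sigma)
  list(genes = gene_models(exons),
       fpkm = data.frame(gene_id = truth$gene_id, fpkm = fpkm,
                         stringsAsFactors = FALSE),
       truth = truth)
}

#' Run the full simulation and write all study files
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   simulation objects (`sim`, `chip`, `expr`).
#' @export
simulate_study <- function(config = simulation_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome(config)
  chip <- generate_chip(sim)
  expr <- generate_expression(sim)
  hits <- truth_hits(sim)
  p <- function(f) file.path(outdir, f)
  writeXStringSet(DNAStringSet(sim$genome), p("genome.fa"))
  write_chrom_sizes(sim$seqinfo, p("chrom.sizes"))
  rtracklayer::export(sim$blacklist, p("blacklist.bed"), format = "BED")
  write_itr_bed(hits, p("itrs.bed"))
  write_elements_bed(pair_itrs(hits), p("elements.bed"))
  write_narrowpeak(chip$peaks, p("peaks.narrowPeak"))
  write_bedgraph(chip$track, p("chip.bedgraph"))
  write_gene_models(expr$genes, p("genes.gtf"))
  write_fpkm(expr$fpkm, p("fpkm.tsv"))
  utils::write.table(chip$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(
    paths = setNames(
      file.path(outdir, c("genome.fa", "chrom.sizes", "blacklist.bed",
                          "itrs.bed", "elements.bed", "peaks.narrowPeak",
                          "chip.bedgraph", "genes.gtf", "fpkm.tsv",
                          "truth.tsv")),
      c("genome", "chrom_sizes", "blacklist", "itrs", "elements", "peaks",
        "bedgraph", "genes", "fpkm", "truth")),
    sim = sim, chip = chip, expr = expr))
}
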