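## Classification of ITR hits into MITE-like paired elements (two hits whose
## inner gap is at most `max_gap`) and solo ITRs.

#' Pair ITR hits into MITEs and solo ITRs
#'
#' Greedy left-to-right pairing per chromosome: each still-unpaired hit pairs
#' with its nearest eligible downstream neighbour, where eligible means
#' unpaired, inner gap (downstream start - upstream end - 1 in 1-based
#' closed coordinates) at most `max_gap`, and, when `require_inverted` is
#' set, `+` upstream / `-` downstream orientation. Every hit ends up in
#' exactly one element.
#'
#' @param hits GRanges of non-overlapping hits (as from [scan_motif()]);
#'   unsorted input is sorted internally.
#' @param max_gap Maximum inner gap in bp (default 500).
#' @param require_inverted Require inverted (+/-) orientation for pairing
#'   (default FALSE: the distance criterion alone decides).
#' @return GRanges of elements spanning the outer coordinates, with metadata
#'   columns `kind` ("MITE"/"solo"), `mm1`, `mm2` (mismatch counts of the
#'   upstream/downstream hit; `mm2` is NA for solos), `profile1`, `profile2`,
#'   `strand1`, `strand2`, and `mm_min`.
#' @export
pair_itrs <- function(hits, max_gap = 500L, require_inverted = FALSE) {
  if (length(hits) && !isDisjoint(hits, ignore.strand = TRUE))
    stop("hits must be non-overlapping")
  hits <- sort(hits, ignore.strand = TRUE)
  n <- length(hits)
  if (n == 0L) {
    el <- GRanges(seqinfo = seqinfo(hits))
    mcols(el) <- DataFrame(kind = character(0), mm1 = integer(0),
                           mm2 = integer(0), profile1 = character(0),
                           profile2 = character(0), strand1 = character(0),
                           strand2 = character(0), mm_min = integer(0))
    return(el)
  }
  chrom <- as.character(seqnames(hits))
  st <- start(hits); en <- end(hits)
  strd <- as.character(strand(hits))
  mm <- mcols(hits)$mismatch_count
  prof <- mcols(hits)$profile
  if (is.null(prof)) prof <- rep(NA_character_, n)

  partner <- rep(NA_integer_, n)
  for (i in seq_len(n - 1L)) {
    if (!is.na(partner[i])) next
    j <- i + 1L
    while (j <= n && chrom[j] == chrom[i] &&
           st[j] - en[i] - 1L <= max_gap) {
      eligible <- is.na(partner[j]) &&
        (!require_inverted || (strd[i] == "+" && strd[j] == "-"))
      if (eligible) {
        partner[i] <- j
        partner[j] <- i
        break
      }
      j <- j + 1L
    }
  }

  first <- which(is.na(partner) | partner > seq_len(n))
  second <- partner[first]
  is_mite <- !is.na(second)
  el_end <- en[first]
  el_end[is_mite] <- en[second[is_mite]]
  el <- GRanges(chrom[first], IRanges(st[first], el_end),
                seqinfo = seqinfo(hits))
  mcols(el) <- DataFrame(
    kind = ifelse(is_mite, "MITE", "solo"),
    mm1 = mm[first],
    mm2 = ifelse(is_mite, mm[second], NA_integer_),
    profile1 = prof[first],
    profile2 = ifelse(is_mite, prof[second], NA_character_),
    strand1 = strd[first],
    strand2 = ifelse(is_mite, strd[second], NA_character_),
    mm_min = ifelse(is_mite, pmin(mm[first], mm[second]), mm[first])
  )
  sort(el, ignore.strand = TRUE)
}

#' Summarize MITE element lengths
#'
#' @param elements GRanges from [pair_itrs()].
#' @return A list with `n_mite`, `median_length` (NA when no MITEs), and
#'   `histogram` (a table of 1-bp binned lengths).
#' @export
element_length_summary <- function(elements) {
  w <- width(elements)[mcols(elements)$kind == "MITE"]
  if (length(w) == 0L) {
    warning("no MITE elements; empty length summary")
    return(list(n_mite = 0L, median_length = NA_real_,
                histogram = table(integer(0))))
  }
  list(n_mite = length(w), median_length = median(w), histogram = table(w))
}

#' Count solo ITRs per mismatch group
#'
#' @param elements GRanges from [pair_itrs()].
#' @param max_mismatch Largest group to report (default 3).
#' @return Named integer vector `"0MM"` ... `"<k>MM"` over solo elements.
#' @export
solo_itrs_by_group <- function(elements, max_mismatch = 3L) {
  solo <- elements[mcols(elements)$kind == "solo"]
  lev <- 0:as.integer(max_mismatch)
  counts <- table(factor(mcols(solo)$mm1, levels = lev))
  setNames(as.integer(counts), paste0(lev, "MM"))
}

#' Write elements as BED
#'
#' MITEs are written as single outer spans named `MITE`; solos as
#' `sITR_<n>MM`. The score column holds `mm_min`.
#'
#' @param elements GRanges from [pair_itrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  kind <- mcols(elements)$kind
  df <- data.frame(
    chrom = as.character(seqnames(elements)),
    start = start(elements) - 1L,
    end = end(elements),
    name = ifelse(kind == "MITE", "MITE",
                  sprintf("sITR_%dMM", mcols(elements)$mm1)),
    score = mcols(elements)$mm_min,
    strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
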