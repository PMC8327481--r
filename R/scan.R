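## Degenerate motif scanner: vectorized Hamming counting over all windows of
## both strands, followed by deterministic greedy overlap resolution.

# Per-window mismatch counts of `motif_raw` against every window of `x_raw`.
# Returns list(mm = integer mismatch count per window, bad = logical, TRUE
# when the window contains a base outside A/C/G/T).
.window_mismatches <- function(x_raw, motif_raw) {
  L <- length(x_raw)
  w <- length(motif_raw)
  nw <- L - w + 1L
  if (nw < 1L)
    return(list(mm = integer(0), bad = logical(0)))
  ok <- x_raw == charToRaw("A") | x_raw == charToRaw("C") |
    x_raw == charToRaw("G") | x_raw == charToRaw("T")
  mm <- integer(nw)
  bad <- logical(nw)
  for (j in seq_len(w)) {
    idx <- j:(j + nw - 1L)
    sub <- x_raw[idx]
    mm <- mm + (sub != motif_raw[j])
    bad <- bad | !ok[idx]
  }
  list(mm = mm, bad = bad)
}

# Greedy overlap resolution: candidates ordered by (mismatch count, strand +
# before -, leftmost start); a candidate is kept iff it does not overlap an
# already-kept hit. `starts` are 1-based, all windows have width `w`,
# `L` is the chromosome length.
.resolve_candidates <- function(starts, strands, mm, L, w) {
  ord <- order(mm, strands != "+", starts)
  taken <- logical(L)
  keep <- logical(length(starts))
  for (i in ord) {
    s <- starts[i]
    span <- s:(s + w - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  keep
}

.coerce_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readDNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("genome must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    stop("chromosome names must be unique")
  toupper(seqs)
}

#' Scan a genome for degenerate motif matches on both strands
#'
#' Slides the motif over every window of every chromosome, on both strands,
#' and reports windows within `max_mismatch` Hamming distance of the motif.
#' Windows containing any base outside A/C/G/T (e.g. N) are never hits.
#' Overlapping raw matches are resolved greedily: the candidate with the
#' lowest mismatch count wins, ties broken by strand (+ over -) then leftmost
#' start, so the returned hits are mutually non-overlapping per chromosome.
#'
#' @param genome A named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA file path. Sequences are
#'   uppercased; soft-masking is ignored.
#' @param motif A [motif_spec()] (default: 19-nt ITR core, up to 3
#'   mismatches).
#' @return A [GenomicRanges::GRanges] sorted by (chromosome, start) with
#'   metadata columns `mismatch_count`, `matched_seq` (oriented: for `-`
#'   strand hits the reverse complement of the genomic window) and `profile`
#'   (see [profile_string()]). Seqlengths are set from the genome.
#' @examples
#' scan_motif(c(chr1 = "GGTGCAAAAGTAATTGCGG"))
#' @export
scan_motif <- function(genome, motif = motif_spec()) {
  motif <- .as_motif(motif)
  seqs <- .coerce_genome(genome)
  w <- motif$length
  fwd_raw <- charToRaw(motif$sequence)
  rev_raw <- charToRaw(revcomp(motif$sequence))

  per_chrom <- lapply(names(seqs), function(chrom) {
    s <- seqs[[chrom]]
    L <- nchar(s)
    if (L < w) return(NULL)
    x_raw <- charToRaw(s)
    fw <- .window_mismatches(x_raw, fwd_raw)
    rv <- .window_mismatches(x_raw, rev_raw)
    fi <- which(!fw$bad & fw$mm <= motif$max_mismatch)
    ri <- which(!rv$bad & rv$mm <= motif$max_mismatch)
    if (length(fi) + length(ri) == 0L) return(NULL)
    starts <- c(fi, ri)
    strands <- rep(c("+", "-"), c(length(fi), length(ri)))
    mm <- c(fw$mm[fi], rv$mm[ri])
    keep <- .resolve_candidates(starts, strands, mm, L, w)
    starts <- starts[keep]; strands <- strands[keep]; mm <- mm[keep]
    o <- order(starts)
    starts <- starts[o]; strands <- strands[o]; mm <- mm[o]
    win <- substring(s, starts, starts + w - 1L)
    oriented <- ifelse(strands == "-", vapply(win, revcomp, ""), win)
    data.frame(chrom = chrom, start = starts, strand = strands, mm = mm,
               matched_seq = unname(oriented), stringsAsFactors = FALSE)
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, TRUE)]
  si <- Seqinfo(seqnames = names(seqs), seqlengths = nchar(seqs))

  if (length(per_chrom) == 0L) {
    gr <- GRanges(seqinfo = si)
    mcols(gr) <- DataFrame(mismatch_count = integer(0),
                           matched_seq = character(0),
                           profile = character(0))
    return(gr)
  }
  df <- do.call(rbind, per_chrom)
  prof <- vapply(df$matched_seq, function(ms)
    profile_string(mismatch_profile(ms, motif)), "")
  gr <- GRanges(df$chrom, IRanges(df$start, width = w), strand = df$strand,
                mismatch_count = df$mm, matched_seq = df$matched_seq,
                profile = unname(prof), seqinfo = si)
  sort(gr, ignore.strand = TRUE)
}

#' Tabulate hits per mismatch group
#'
#' @param hits GRanges from [scan_motif()].
#' @param max_mismatch Largest group to report (default 3).
#' @return Named integer vector with entries `"0MM"` ... `"<k>MM"`, summing
#'   to `length(hits)`.
#' @export
group_by_mismatch <- function(hits, max_mismatch = 3L) {
  max_mismatch <- as.integer(max_mismatch)
  lev <- 0:max_mismatch
  mm <- mcols(hits)$mismatch_count
  if (length(mm) && any(mm > max_mismatch))
    stop("hits contain mismatch counts above max_mismatch")
  counts <- table(factor(mm, levels = lev))
  setNames(as.integer(counts), paste0(lev, "MM"))
}
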