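# Naive all-windows oracle for the degenerate scanner, independent of the
# package's vectorized implementation: explicit per-window character
# comparison, with the minus strand checked by reverse-complementing each
# window.

.comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_raw_matches <- function(seqs, motif = ITR_CORE_MOTIF,
                               max_mismatch = 3L) {
  mchars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  w <- length(mchars)
  out_chrom <- character(0); out_start <- integer(0)
  out_strand <- character(0); out_mm <- integer(0)
  for (chrom in names(seqs)) {
    chars <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1L]]
    L <- length(chars)
    if (L < w) next
    valid <- chars %in% c("A", "C", "G", "T")
    for (s in seq_len(L - w + 1L)) {
      idx <- s:(s + w - 1L)
      if (!all(valid[idx])) next
      win <- chars[idx]
      mm_f <- sum(win != mchars)
      if (mm_f <= max_mismatch) {
        out_chrom <- c(out_chrom, chrom); out_start <- c(out_start, s)
        out_strand <- c(out_strand, "+"); out_mm <- c(out_mm, mm_f)
      }
      rc_win <- rev(unname(.comp[win]))
      mm_r <- sum(rc_win != mchars)
      if (mm_r <= max_mismatch) {
        out_chrom <- c(out_chrom, chrom); out_start <- c(out_start, s)
        out_strand <- c(out_strand, "-"); out_mm <- c(out_mm, mm_r)
      }
    }
  }
  data.frame(chrom = out_chrom, start = out_start, strand = out_strand,
             mm = out_mm, stringsAsFactors = FALSE)
}

# Independent greedy resolution: lowest mismatch first, + before -, then
# leftmost; quadratic overlap check against accepted hits.
oracle_resolve <- function(df, width = 19L) {
  if (nrow(df) == 0L) return(df)
  out <- df[0, , drop = FALSE]
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$mm, d$strand, d$start), , drop = FALSE]
    acc <- d[0, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      s <- d$start[i]
      if (nrow(acc) == 0L ||
          all(s + width - 1L < acc$start | s > acc$start + width - 1L))
        acc <- rbind(acc, d[i, , drop = FALSE])
    }
    out <- rbind(out, acc)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_scan <- function(seqs, motif = ITR_CORE_MOTIF, max_mismatch = 3L) {
  oracle_resolve(oracle_raw_matches(seqs, motif, max_mismatch),
                 width = nchar(motif))
}

hits_to_df <- function(hits) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(hits)),
                   start = BiocGenerics::start(hits),
                   strand = as.character(BiocGenerics::strand(hits)),
                   mm = S4Vectors::mcols(hits)$mismatch_count,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_genome <- function(seed, lengths = c(chr1 = 10000L)) {
  set.seed(seed)
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
}

# Plant a motif variant (oriented sequence `var`) at `pos` (1-based) of a
# background string; minus strand inserts the reverse complement.
plant <- function(background, var, pos, strand = "+") {
  ins <- if (strand == "+") var else revcomp(var)
  paste0(substr(background, 1, pos - 1L), ins,
         substr(background, pos + nchar(ins), nchar(background)))
}

# Small constant-valued track helper.
flat_track <- function(lengths, value = 0) {
  as(lapply(lengths, function(L) S4Vectors::Rle(value, L)), "RleList")
}
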