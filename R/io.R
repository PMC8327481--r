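## Readers and writers for the plain-text formats the pipeline consumes and
## emits. Parsing goes through rtracklayer/Biostrings; the BED6+2 hit format
## (extra columns matched_seq, profile) is written directly.

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] with names trimmed to the first
#'   whitespace-delimited token.
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write ITR hits as BED6+2
#'
#' Columns: chrom, start (0-based), end, name (`ITR_<n>MM`), score
#' (mismatch count), strand, matched_seq, profile (`.` when empty).
#'
#' @param hits GRanges from [scan_motif()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_itr_bed <- function(hits, path) {
  prof <- mcols(hits)$profile
  df <- data.frame(
    chrom = as.character(seqnames(hits)),
    start = start(hits) - 1L,
    end = end(hits),
    name = sprintf("ITR_%dMM", mcols(hits)$mismatch_count),
    score = mcols(hits)$mismatch_count,
    strand = as.character(strand(hits)),
    matched_seq = mcols(hits)$matched_seq,
    profile = ifelse(is.na(prof) | prof == "", ".", prof)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ITR hits from BED6+2
#'
#' @param path File written by [write_itr_bed()].
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo] carrying chromosome
#'   lengths.
#' @return GRanges with metadata columns `mismatch_count`, `matched_seq`,
#'   `profile`.
#' @export
read_itr_bed <- function(path, seqinfo = NULL) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(matched_seq = "character",
                                          profile = "character"))
  out <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
  mcols(out)$mismatch_count <- as.integer(gr$score)
  mcols(out)$matched_seq <- gr$matched_seq
  mcols(out)$profile <- ifelse(is.na(gr$profile) | gr$profile == ".", "",
                               gr$profile)
  if (!is.null(seqinfo)) {
    seqlevels(out) <- seqlevels(seqinfo)
    seqinfo(out) <- seqinfo
  }
  sort(out, ignore.strand = TRUE)
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV (chromosome, length), no header.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"))
  Seqinfo(seqnames = as.character(df$chrom),
          seqlengths = as.integer(df$length))
}

#' Write chromosome sizes
#'
#' @param seqinfo A [GenomeInfoDb::Seqinfo] (or object with one).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(seqinfo, path) {
  if (!is(seqinfo, "Seqinfo")) seqinfo <- seqinfo(seqinfo)
  write.table(
    data.frame(chrom = seqlevels(seqinfo),
               length = unname(seqlengths(seqinfo))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ChIP peaks (narrowPeak or BED6)
#'
#' For narrowPeak input the summit is `start + peak offset` (column 10); for
#' a missing offset (`-1`) or plain BED the interval midpoint is used.
#'
#' @param path Peak file path.
#' @param format `"narrowPeak"` or `"bed"`.
#' @param seqinfo Optional Seqinfo for chromosome bounds.
#' @return GRanges with metadata columns `name`, `score` and `summit`
#'   (absolute 1-based position, `start <= summit <= end`).
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed"),
                       seqinfo = NULL) {
  format <- match.arg(format)
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(signalValue = "numeric",
                                            pValue = "numeric",
                                            qValue = "numeric",
                                            peak = "integer"))
    summit <- ifelse(gr$peak >= 0L, start(gr) + gr$peak,
                     (start(gr) + end(gr)) %/% 2L)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    summit <- (start(gr) + end(gr)) %/% 2L
  }
  out <- GRanges(seqnames(gr), ranges(gr))
  mcols(out)$name <- if (!is.null(gr$name)) gr$name else
    paste0("peak_", seq_along(gr))
  mcols(out)$score <- if (!is.null(gr$score)) as.numeric(gr$score) else 0
  mcols(out)$summit <- as.integer(summit)
  if (!is.null(seqinfo)) {
    seqlevels(out) <- seqlevels(seqinfo)
    seqinfo(out) <- seqinfo
  }
  sort(out)
}

#' Write peaks in narrowPeak format
#'
#' @param peaks GRanges with metadata columns `name`, `score`, `summit`, and
#'   optionally `signalValue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  sv <- mcols(peaks)$signalValue
  if (is.null(sv)) sv <- mcols(peaks)$score
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = mcols(peaks)$name,
    score = round(mcols(peaks)$score),
    strand = ".",
    signalValue = sv,
    pValue = -1,
    qValue = -1,
    peak = mcols(peaks)$summit - start(peaks)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base signal track from bedGraph
#'
#' @param path bedGraph file path (sorted, non-overlapping intervals).
#' @param seqinfo A [GenomeInfoDb::Seqinfo] giving chromosome lengths
#'   (required so uncovered trailing bases score 0).
#' @return A named [IRanges::RleList], one numeric Rle per chromosome.
#' @export
read_bedgraph <- function(path, seqinfo) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(gr, seqinfo)
}

#' Build a signal track from scored intervals
#'
#' Converts bedGraph-style scored, non-overlapping intervals into a per-base
#' run-length encoded track; uncovered bases score 0.
#'
#' @param x GRanges with a numeric `score` column, non-overlapping.
#' @param seqinfo A [GenomeInfoDb::Seqinfo] with lengths for every
#'   chromosome.
#' @return A named [IRanges::RleList].
#' @export
signal_track <- function(x, seqinfo) {
  if (!is(seqinfo, "Seqinfo")) seqinfo <- seqinfo(seqinfo)
  if (is.null(mcols(x)$score)) stop("intervals need a 'score' column")
  if (!all(as.character(seqnames(x)) %in% seqlevels(seqinfo)))
    stop("interval chromosomes missing from seqinfo")
  red <- reduce(x, ignore.strand = TRUE)
  if (sum(width(red)) != sum(width(x)))
    stop("signal intervals must be non-overlapping")
  seqlevels(x) <- seqlevels(seqinfo)
  seqinfo(x) <- seqinfo
  coverage(x, weight = "score")
}

#' Write a signal track as bedGraph
#'
#' @param track An [IRanges::RleList] (see [signal_track()]).
#' @param path Output path.
#' @param drop_zero Omit zero-valued runs (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  gr <- as(track, "GRanges")
  if (drop_zero) gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read an expression table
#'
#' @param path TSV with header columns `gene_id` and `fpkm`.
#' @return data.frame with columns `gene_id`, `fpkm`.
#' @export
read_fpkm <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(df)))
    stop("expression table needs columns 'gene_id' and 'fpkm'")
  if (any(df$fpkm < 0)) stop("FPKM values must be non-negative")
  df[c("gene_id", "fpkm")]
}

#' Write an expression table
#'
#' @param df data.frame with `gene_id`, `fpkm`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(df, path) {
  write.table(df[c("gene_id", "fpkm")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
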