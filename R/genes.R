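## Gene models: per-gene span + exon structure, with strand-aware TSS/TTS
## windows used for summit annotation and gene association.

#' Build gene models from exons
#'
#' @param exons GRanges of exons carrying a `gene_id` metadata column and
#'   strand; exons of a gene must lie on one chromosome and strand.
#' @return An object of class `gene_models`: a list with `genes` (GRanges,
#'   one range per gene spanning its exons, metadata `gene_id`) and `exons`
#'   (GRangesList named by gene id).
#' @export
gene_models <- function(exons) {
  if (is.null(mcols(exons)$gene_id)) stop("exons need a 'gene_id' column")
  gid <- as.character(mcols(exons)$gene_id)
  key <- paste(as.character(seqnames(exons)), as.character(strand(exons)))
  if (any(tapply(key, gid, function(x) length(unique(x))) != 1L))
    stop("exons of one gene must share chromosome and strand")
  ex <- split(exons, gid)
  if (!all(isDisjoint(ex)))
    stop("exons of one gene must be non-overlapping")
  genes <- unlist(range(ex))
  mcols(genes)$gene_id <- names(genes)
  names(genes) <- NULL
  structure(list(genes = genes, exons = ex), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,",
      sum(lengths(x$exons)), "exons\n")
  invisible(x)
}

#' Read gene models from GTF
#'
#' @param path GTF file; exon records with a `gene_id` attribute are used.
#' @param seqinfo Optional Seqinfo for chromosome bounds.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, seqinfo = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon records in ", path)
  if (!is.null(seqinfo)) {
    seqlevels(ex) <- seqlevels(seqinfo)
    seqinfo(ex) <- seqinfo
  }
  gene_models(ex)
}

#' Write gene models as GTF
#'
#' Emits gene, transcript (one per gene) and exon records.
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  genes <- models$genes
  ex <- unlist(models$exons)
  gid_ex <- names(ex)
  names(ex) <- NULL
  rows <- function(gr, type, gid) {
    GRanges(seqnames(gr), ranges(gr), strand = strand(gr),
            source = "itrtools", type = type, gene_id = gid,
            transcript_id = paste0(gid, ".t1"))
  }
  out <- c(rows(genes, "gene", genes$gene_id),
           rows(genes, "transcript", genes$gene_id),
           rows(ex, "exon", gid_ex))
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

# Strand-aware TSS windows: [tss - up, tss + down] on +, mirrored on -.
.tss_windows <- function(genes, up = 1000L, down = 100L) {
  tss <- resize(genes, width = 1L, fix = "start")
  suppressWarnings(trim(promoters(tss, upstream = up, downstream = down + 1L)))
}

# Strand-aware TTS windows: [tts - up, tts + down] on +, mirrored on -.
.tts_windows <- function(genes, up = 100L, down = 1000L) {
  tts <- resize(genes, width = 1L, fix = "end")
  suppressWarnings(trim(promoters(tts, upstream = up, downstream = down + 1L)))
}
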