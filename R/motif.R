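#' The Hsmar1 ITR core motif
#'
#' The 19-nt core of the \emph{Hsmar1} inverted terminal repeat,
#' 5'-GGTGCAAAAGTAATTGCGG-3', the in vitro binding site of the SETMAR
#' transposase domain.
#'
#' @format A length-one character string.
#' @export
ITR_CORE_MOTIF <- "GGTGCAAAAGTAATTGCGG"

#' Specify a motif for degenerate scanning
#'
#' Bundles a DNA motif with the maximum number of mismatches tolerated when
#' scanning. The default is the 19-nt ITR core with up to 3 mismatches.
#'
#' @param sequence DNA string over the alphabet A/C/G/T.
#' @param max_mismatch Non-negative integer, strictly less than the motif
#'   length.
#' @return An object of class `motif_spec` with elements `sequence`,
#'   `max_mismatch` and `length`.
#' @examples
#' motif_spec()
#' motif_spec("ACGT", 1)
#' @export
motif_spec <- function(sequence = ITR_CORE_MOTIF, max_mismatch = 3L) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("motif sequence must be a single non-empty string")
  if (grepl("[^ACGT]", sequence))
    stop("motif sequence may only contain A, C, G, T")
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L)
    stop("max_mismatch must be a non-negative integer")
  if (max_mismatch >= nchar(sequence))
    stop("max_mismatch must be smaller than the motif length")
  structure(
    list(sequence = sequence, max_mismatch = max_mismatch,
         length = nchar(sequence)),
    class = "motif_spec"
  )
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("motif_spec: 5'-", x$sequence, "-3' (", x$length,
      " nt), max mismatches ", x$max_mismatch, "\n", sep = "")
  invisible(x)
}

.as_motif <- function(motif) {
  if (inherits(motif, "motif_spec")) motif else motif_spec(motif)
}

#' Reverse-complement a DNA string
#'
#' @param x DNA character string.
#' @return The reverse complement as a character string.
#' @examples
#' revcomp("GGTGCAAAAGTAATTGCGG")
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

#' Mismatch profile of a window against a motif
#'
#' Compares an oriented window (same length and orientation as the motif)
#' position by position and reports every differing position in 1-based motif
#' coordinates, matching the field's "C17"-style position naming (motif base
#' plus position).
#'
#' @param window Oriented DNA string, same length as the motif.
#' @param motif A [motif_spec()] or motif string.
#' @return A data.frame with columns `position`, `motif_base`,
#'   `observed_base`, one row per mismatch, ordered by position.
#' @examples
#' mismatch_profile("GGTGCAAAAGTAATTGTGG", motif_spec())
#' @export
mismatch_profile <- function(window, motif = motif_spec()) {
  motif <- .as_motif(motif)
  window <- toupper(as.character(window))
  if (nchar(window) != motif$length)
    stop("window length (", nchar(window), ") differs from motif length (",
         motif$length, ")")
  wm <- strsplit(motif$sequence, "", fixed = TRUE)[[1L]]
  wo <- strsplit(window, "", fixed = TRUE)[[1L]]
  idx <- which(wm != wo)
  data.frame(position = idx, motif_base = wm[idx], observed_base = wo[idx],
             stringsAsFactors = FALSE)
}

#' Serialize a mismatch profile to a compact string
#'
#' @param profile A data.frame from [mismatch_profile()].
#' @return A string like `"17:C>T"` (comma-separated for several mismatches),
#'   or `""` for a perfect match.
#' @export
profile_string <- function(profile) {
  if (nrow(profile) == 0L) return("")
  paste0(profile$position, ":", profile$motif_base, ">",
         profile$observed_base, collapse = ",")
}

#' Parse a mismatch profile string
#'
#' Inverse of [profile_string()].
#'
#' @param x Profile string, e.g. `"2:G>A,18:G>A"`; `""` or `"."` mean no
#'   mismatches.
#' @return A data.frame with columns `position`, `motif_base`,
#'   `observed_base`.
#' @export
parse_profile <- function(x) {
  if (is.na(x) || x == "" || x == ".")
    return(data.frame(position = integer(0), motif_base = character(0),
                      observed_base = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+):([ACGT])>([ACGT])$", parts))
  if (any(lengths(m) != 4L)) stop("malformed profile string: ", x)
  data.frame(
    position = as.integer(vapply(m, `[`, "", 2L)),
    motif_base = vapply(m, `[`, "", 3L),
    observed_base = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}
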