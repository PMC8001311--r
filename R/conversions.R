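# Strand-aware classification of RNA-DNA differences into the 12
# transcript-level conversion types.

.CONVERSION_TYPES <- c(
  "G-to-A", "C-to-U", "U-to-C", "U-to-A", "A-to-G", "C-to-A",
  "A-to-U", "G-to-U", "C-to-G", "A-to-C", "G-to-C", "U-to-G"
)

.complement_base <- function(x) chartr("ACGT", "TGCA", x)
.dna_to_rna <- function(x) chartr("T", "U", x)
.rna_to_dna <- function(x) chartr("U", "T", x)

#' The twelve transcript-level conversion types
#'
#' An RNA-DNA difference is an ordered pair (reference base, transcript base)
#' over the RNA alphabet `{A, C, G, U}`; there are exactly 4 x 3 = 12 such
#' pairs.  Conversions are always reported on the transcript strand, so a
#' genomic T-to-C difference in a gene on the plus strand and a genomic
#' A-to-G difference in a gene on the minus strand are the same transcript
#' event, U-to-C.
#'
#' @return Character vector of the 12 conversion labels, e.g. `"U-to-C"`.
#' @export
#' @examples
#' conversion_types()
conversion_types <- function() .CONVERSION_TYPES

#' Classify a genomic reference/alternate base pair as a transcript conversion
#'
#' Maps a genomic substitution onto the transcript strand: on `"-"` strand
#' genes both bases are complemented first, then DNA T is rewritten as RNA U.
#' Vectorised over all three arguments.
#'
#' @param ref Genomic reference base(s), one of `A`, `C`, `G`, `T`.
#' @param alt Genomic alternate base(s); must differ from `ref` elementwise.
#' @param strand `"+"` or `"-"`, the strand of the transcript the site lies in.
#' @return Character vector of conversion labels (see [conversion_types()]).
#' @export
#' @examples
#' classify_conversion("T", "C", "+")  # "U-to-C"
#' classify_conversion("A", "G", "-")  # also "U-to-C"
classify_conversion <- function(ref, alt, strand) {
  n <- max(length(ref), length(alt), length(strand))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(ref %in% c("A", "C", "G", "T")) || !all(alt %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single DNA bases (A/C/G/T)")
  if (any(ref == alt))
    stop("ref and alt must differ")
  minus <- strand == "-"
  ref[minus] <- .complement_base(ref[minus])
  alt[minus] <- .complement_base(alt[minus])
  paste0(.dna_to_rna(ref), "-to-", .dna_to_rna(alt))
}

#' Normalise a conversion label to the RNA-alphabet spelling
#'
#' Accepts mixed DNA/RNA spellings such as `"A-to-T"`, `"T-to-C"` or
#' `"G-to-T"` and rewrites them over the RNA alphabet (`"A-to-U"`,
#' `"U-to-C"`, `"G-to-U"`).  Unknown labels are an error.
#'
#' @param x Character vector of conversion labels.
#' @return Character vector of canonical labels.
#' @export
normalize_conversion <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("\\s+", "", x)
  x <- sub("^([ACGTU])-?TO-?([ACGTU])$", "\\1-to-\\2", x)
  x <- sub("TO", "to", x, fixed = TRUE)
  out <- .dna_to_rna(substr(x, 1, 1))
  out <- paste0(out, "-to-", .dna_to_rna(substr(x, nchar(x), nchar(x))))
  bad <- !(out %in% .CONVERSION_TYPES)
  if (any(bad))
    stop("unrecognised conversion label(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

# Genomic (ref, alt) DNA pair realising a transcript conversion on a strand.
.conversion_to_dna <- function(conversion, strand) {
  conversion <- normalize_conversion(conversion)
  n <- max(length(conversion), length(strand))
  conversion <- rep_len(conversion, n)
  strand <- rep_len(strand, n)
  ref <- .rna_to_dna(substr(conversion, 1, 1))
  alt <- .rna_to_dna(substr(conversion, 6, 6))
  minus <- strand == "-"
  ref[minus] <- .complement_base(ref[minus])
  alt[minus] <- .complement_base(alt[minus])
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}
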