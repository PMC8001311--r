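# Read quality control: the filters defining "clean reads".
#
# A read is discarded when (in this order) it is empty, contains the adapter,
# has strictly more than 10% uncertain (N) bases, or has strictly more than
# 50% of its bases below Phred 20.  Both fraction thresholds are strict
# inequalities, so a 100-base read with exactly 10 Ns or exactly 50 low-
# quality bases is kept.

.QC_REASONS <- c("empty", "adapter", "N>10%", "low-quality")

#' Quality-control parameters
#'
#' @param adapter_sequence Adapter to detect by exact substring match.
#' @param n_fraction_max Maximum tolerated N fraction (discard when strictly
#'   above).
#' @param lowq_threshold Phred score below which a base counts as low
#'   quality.
#' @param lowq_fraction_max Maximum tolerated fraction of low-quality bases
#'   (discard when strictly above).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(adapter_sequence = "AGATCGGAAGAGC",
                      n_fraction_max = 0.10,
                      lowq_threshold = 20L,
                      lowq_fraction_max = 0.50) {
  if (n_fraction_max < 0 || n_fraction_max > 1 ||
      lowq_fraction_max < 0 || lowq_fraction_max > 1)
    stop("fractions must lie in [0, 1]")
  structure(list(adapter_sequence = toupper(adapter_sequence),
                 n_fraction_max = n_fraction_max,
                 lowq_threshold = as.integer(lowq_threshold),
                 lowq_fraction_max = lowq_fraction_max),
            class = "qc_params")
}

# Vectorised reason codes ("keep" or the first failing rule, in rule order).
.qc_reasons <- function(reads, params) {
  seq <- toupper(reads$seq)
  len <- nchar(seq)
  n_count <- len - nchar(gsub("N", "", seq, fixed = TRUE))
  lowq_frac <- vapply(reads$qual, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q) - 33L < params$lowq_threshold)
  }, numeric(1), USE.NAMES = FALSE)
  reason <- rep("keep", length(seq))
  reason[lowq_frac > params$lowq_fraction_max] <- "low-quality"
  reason[n_count / pmax(len, 1L) > params$n_fraction_max] <- "N>10%"
  reason[grepl(params$adapter_sequence, seq, fixed = TRUE)] <- "adapter"
  reason[len == 0L] <- "empty"
  reason
}

#' Filter a single read
#'
#' @param read A list or one-row data frame with elements `seq` and `qual`
#'   (Phred+33 quality string of equal length).
#' @param params A [qc_params()] object.
#' @return List with `keep` (logical) and `reason` (`"keep"`, `"empty"`,
#'   `"adapter"`, `"N>10%"` or `"low-quality"`; the first failing rule in
#'   that order).
#' @export
#' @examples
#' filter_read(list(seq = strrep("N", 11L), qual = strrep("F", 11L)),
#'             qc_params())
filter_read <- function(read, params = qc_params()) {
  df <- data.frame(seq = read$seq, qual = read$qual, stringsAsFactors = FALSE)
  if (nchar(df$seq) != nchar(df$qual))
    stop("sequence and quality strings must have equal length")
  reason <- .qc_reasons(df, params)
  list(keep = reason == "keep", reason = reason)
}

#' Filter a read set (optionally paired)
#'
#' In paired-end mode both mates are discarded when either fails any rule;
#' the surviving mate is counted under reason `"mate"`.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param params A [qc_params()] object.
#' @param pair_id Optional vector grouping mates; reads sharing a `pair_id`
#'   live or die together.
#' @return `reads` with the failing rows removed; the per-read reason codes
#'   are attached as attribute `"reason"` (aligned with the input rows).
#' @export
qc_filter <- function(reads, params = qc_params(), pair_id = NULL) {
  reason <- .qc_reasons(reads, params)
  if (!is.null(pair_id)) {
    stopifnot(length(pair_id) == nrow(reads))
    bad_pair <- unique(pair_id[reason != "keep"])
    mate <- reason == "keep" & pair_id %in% bad_pair
    reason[mate] <- "mate"
  }
  out <- reads[reason == "keep", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reason") <- reason
  out
}

#' Quality-control summary
#'
#' Tabulates kept and discarded reads by reason.  The counts always satisfy
#' `kept + sum(discarded) = total` and are invariant to the input order.
#'
#' @inheritParams qc_filter
#' @return A list of class `qc_summary`: `total`, `kept` and `discarded`
#'   (named vector over the reason codes).
#' @export
qc_summary <- function(reads, params = qc_params(), pair_id = NULL) {
  reasons_all <- c(.QC_REASONS, if (!is.null(pair_id)) "mate")
  if (nrow(reads) == 0L) {
    disc <- setNames(integer(length(reasons_all)), reasons_all)
    res <- list(total = 0L, kept = 0L, discarded = disc)
  } else {
    kept <- qc_filter(reads, params, pair_id)
    reason <- attr(kept, "reason")
    disc <- vapply(reasons_all, function(r) sum(reason == r), integer(1))
    res <- list(total = nrow(reads), kept = nrow(kept), discarded = disc)
  }
  class(res) <- "qc_summary"
  res
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("reads: %d total, %d kept (%.1f%%)\n", x$total, x$kept,
              if (x$total) 100 * x$kept / x$total else 0))
  for (r in names(x$discarded))
    if (x$discarded[[r]] > 0)
      cat(sprintf("  discarded [%s]: %d\n", r, x$discarded[[r]]))
  invisible(x)
}

#' FASTQ input/output
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] converting to and from the plain
#' `id`/`seq`/`qual` data-frame representation used throughout the package
#' (Phred+33 qualities).
#'
#' @param path FASTQ path.
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @return `read_fastq()` a reads data frame; `write_fastq()` the path,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write a QC report TSV
#'
#' @param summaries Named list of [qc_summary()] results (one per sample).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(summaries, path) {
  rows <- lapply(names(summaries), function(s) {
    x <- summaries[[s]]
    data.frame(sample = s, total = x$total, kept = x$kept,
               t(x$discarded), check.names = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
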