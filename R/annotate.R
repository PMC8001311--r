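# Feature annotation of genomic positions, gene-list intersection and the
# candidate/validated ledger I/O.

# Vectorised feature lookup; returns data.frame(feature, gene_id, strand).
# Overlapping models are resolved deterministically: first by start, ties by
# gene_id.  Positions outside all models are "intergenic" on strand "+".
.feature_at <- function(contig, pos, gene_models) {
  n <- length(pos)
  out <- data.frame(feature = rep("intergenic", n),
                    gene_id = rep(NA_character_, n),
                    strand = rep("+", n), stringsAsFactors = FALSE)
  if (is.null(gene_models) || !nrow(gene_models)) return(out)
  gm <- gene_models[order(gene_models$start, gene_models$gene_id), , drop = FALSE]
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L))
  s <- GenomicRanges::GRanges(gm$contig, IRanges::IRanges(gm$start, gm$end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    first <- !duplicated(qh)  # subjects sorted by (start, gene_id)
    out$feature[qh[first]] <- gm$feature[sh[first]]
    out$gene_id[qh[first]] <- gm$gene_id[sh[first]]
    out$strand[qh[first]] <- gm$strand[sh[first]]
  }
  out
}

#' Annotate genomic positions with their gene feature
#'
#' Every position receives exactly one label: the feature (`5'UTR`, `CDS`,
#' `3'UTR`, `intron`, ...) of the containing gene-model interval, or
#' `"intergenic"`.  When models overlap, the interval with the smallest
#' start wins (ties broken by lexicographic `gene_id`).
#'
#' @param contig,position Vectors of positions (1-based).
#' @param gene_models Gene-model data frame (see [read_gene_models()]).
#' @return Data frame with columns `feature`, `gene_id`, `strand`.
#' @export
#' @examples
#' gm <- data.frame(contig = "c", start = c(1, 51), end = c(50, 90),
#'                  strand = "+", feature = c("5'UTR", "CDS"),
#'                  gene_id = "G1")
#' annotate_feature("c", c(10, 60, 95), gm)
annotate_feature <- function(contig, position, gene_models) {
  .feature_at(rep_len(as.character(contig), length(position)),
              as.integer(position), gene_models)
}

#' Fraction of candidates located in UTRs
#'
#' @param candidates Data frame with a `feature` column.
#' @param exclude_intergenic Drop intergenic candidates from the denominator.
#' @return Fraction in `[0, 1]`, or `NA` when the denominator is empty.
#' @export
utr_fraction <- function(candidates, exclude_intergenic = FALSE) {
  feats <- candidates$feature
  if (exclude_intergenic) feats <- feats[feats != "intergenic"]
  if (!length(feats)) return(NA_real_)
  mean(feats %in% c("5'UTR", "3'UTR"))
}

#' Intersect candidate gene identifiers with an external gene list
#'
#' Identifiers are case-normalised and whitespace-trimmed on both sides; the
#' overlap is returned sorted for stable output.
#'
#' @param candidate_gene_ids Character vector (e.g. `gene_id` column of a
#'   candidate table); `NA`s are dropped.
#' @param gene_list Character vector of identifiers (e.g. an expressed-PPR
#'   list from [read_gene_list()]).
#' @return List with `overlap` (sorted character vector), `n_candidates`,
#'   `n_list`, `n_overlap`.
#' @export
intersect_gene_list <- function(candidate_gene_ids, gene_list) {
  norm <- function(x) unique(toupper(trimws(x[!is.na(x)])))
  cand <- norm(candidate_gene_ids)
  gl <- norm(gene_list)
  ov <- sort(intersect(cand, gl))
  list(overlap = ov, n_candidates = length(cand), n_list = length(gl),
       n_overlap = length(ov))
}

#' Read a gene list (one identifier per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

.read_ledger <- function(path, columns, numeric_cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty ledger file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(columns, header)
  if (length(miss))
    stop("ledger lacks column(s): ", paste(miss, collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  rows <- lapply(seq_along(body), function(i) {
    f <- body[[i]]
    if (length(f) != length(header))
      stop(sprintf("malformed row at line %d of %s: %d field(s), expected %d",
                   i + 1L, path, length(f), length(header)))
    f
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (cn in intersect(numeric_cols, header)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed row at line %d of %s: non-numeric '%s' in column %s",
                   bad + 1L, path, df[[cn]][bad], cn))
    }
    df[[cn]] <- if (all(v == round(v))) as.integer(v) else v
  }
  df
}

#' Candidate-site ledger I/O
#'
#' The candidate ledger is a tab-separated table with columns `sno`,
#' `position`, one `reads_<sample>` column per sample (alternate-supporting
#' read counts), `gene_id` and `description`.  Writing then reading a table
#' reproduces it exactly; the packaged transcription of a published 56-row
#' candidate list is available under
#' `system.file("extdata", "candidate_sites_table.tsv", package = "uceditr")`.
#'
#' @param path TSV path.
#' @param x Candidate-table data frame.
#' @return `read_candidate_table()` the parsed data frame;
#'   `write_candidate_table()` the path, invisibly.
#' @export
read_candidate_table <- function(path) {
  df <- .read_ledger(path, c("sno", "position", "gene_id", "description"),
                     numeric_cols = c("sno", "position"))
  reads_cols <- grep("^reads_", names(df), value = TRUE)
  if (!length(reads_cols))
    stop("candidate ledger lacks reads_<sample> column(s)")
  for (cn in reads_cols) {
    v <- suppressWarnings(as.integer(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed row at line %d of %s: non-numeric '%s' in column %s",
                   bad + 1L, path, df[[cn]][bad], cn))
    }
    df[[cn]] <- v
  }
  df
}

#' @rdname read_candidate_table
#' @export
write_candidate_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validated-site ledger I/O
#'
#' The validated ledger mirrors a published validation table: columns `sno`,
#' `position`, `edited_site` (feature label), `gene_id`, one `eff_<sample>`
#' column per sample (editing efficiency in percent) and `encoded_protein`.
#' Efficiency columns are kept as verbatim character strings so that writing
#' reproduces the file byte-for-byte (printed tables fix their decimals);
#' use [validated_efficiencies()] for numeric values.
#'
#' @param path TSV path.
#' @param x Validated-table data frame.
#' @return `read_validated_table()` the parsed data frame (efficiencies as
#'   character); `write_validated_table()` the path, invisibly.
#' @export
read_validated_table <- function(path) {
  df <- .read_ledger(path, c("sno", "position", "edited_site", "gene_id",
                             "encoded_protein"),
                     numeric_cols = c("sno", "position"))
  eff_cols <- grep("^eff_", names(df), value = TRUE)
  if (!length(eff_cols))
    stop("validated ledger lacks eff_<sample> column(s)")
  for (cn in eff_cols)
    if (anyNA(suppressWarnings(as.numeric(df[[cn]]))))
      stop("non-numeric efficiency in column ", cn, " of ", path)
  df
}

#' @rdname read_validated_table
#' @export
write_validated_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Numeric efficiencies from a validated-site table
#'
#' @param x Table from [read_validated_table()].
#' @param samples Sample names; defaults to every `eff_*` column present.
#' @return Numeric matrix (rows = sites, columns = samples) in percent.
#' @export
validated_efficiencies <- function(x, samples = NULL) {
  if (is.null(samples))
    samples <- sub("^eff_", "", grep("^eff_", names(x), value = TRUE))
  m <- vapply(paste0("eff_", samples), function(cn) as.numeric(x[[cn]]),
              numeric(nrow(x)))
  m <- matrix(m, nrow = nrow(x), dimnames = list(x$gene_id, samples))
  m
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path, or a vector of file names.
#' @export
uceditr_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "uceditr")))
  system.file("extdata", file, package = "uceditr", mustWork = TRUE)
}
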