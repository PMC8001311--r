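# Per-site pileups, RNA-DNA difference calling and the SNP/polymorphism
# filters producing editing candidates.

.BASES <- c("A", "C", "G", "T")

#' Build a per-site pileup from placed reads
#'
#' Tallies, for every reference position covered by at least `min_depth`
#' placed reads, the number of reads supporting each base.  The sum of a
#' site's counts equals the number of reads overlapping it.
#'
#' @param alignments Placement table from [place_reads()].
#' @param reads The reads that were placed (columns `id`, `seq`).
#' @param reference Named [Biostrings::DNAStringSet].
#' @param sample Sample name recorded in the output.
#' @param min_depth Minimum depth for a site to be reported.
#' @return Pileup data frame: `contig`, `pos` (1-based), `ref`, `sample`,
#'   `A`, `C`, `G`, `T`, `N`, `depth`.
#' @export
build_pileup <- function(alignments, reads, reference, sample = "sample1",
                         min_depth = 1L) {
  placed <- alignments[!is.na(alignments$start), , drop = FALSE]
  out <- list()
  for (ci in seq_along(reference)) {
    cname <- names(reference)[ci]
    sel <- placed[placed$contig == cname, , drop = FALSE]
    if (!nrow(sel)) next
    seqs <- reads$seq[match(sel$id, reads$id)]
    Lc <- Biostrings::width(reference)[ci]
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                      shift = sel$start - 1L, width = Lc)
    rows <- intersect(c(.BASES, "N"), rownames(cm))
    cm <- cm[rows, , drop = FALSE]
    depth <- colSums(cm)
    keep <- which(depth >= min_depth)
    if (!length(keep)) next
    refb <- strsplit(as.character(reference[[ci]]), "", fixed = TRUE)[[1]]
    keep <- as.integer(unname(keep))
    df <- data.frame(contig = cname, pos = keep, ref = refb[keep],
                     sample = sample, t(cm[, keep, drop = FALSE]),
                     depth = depth[keep], stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (b in setdiff(c(.BASES, "N"), names(df))) df[[b]] <- 0L
    out[[cname]] <- df[, c("contig", "pos", "ref", "sample", .BASES, "N",
                           "depth")]
  }
  if (!length(out))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), sample = character(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), N = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call RNA-DNA differences from a multi-sample pileup
#'
#' Emits one event per (site, alternate base) whose support reaches
#' `min_alt_reads` reads *and* `min_alt_frac` of the site depth in at least
#' one sample.  Events are annotated with the containing gene and its strand
#' (intergenic sites get strand `"+"` and `gene_id` `NA`) and classified into
#' the transcript-level conversion type.
#'
#' The defaults (2 reads, 5%) keep even weakly supported sites; sites backed
#' by only a couple of reads are rarely confirmed downstream, but raising the
#' floor is a sensitivity/specificity trade the caller controls.
#'
#' @param pileup Pileup data frame (possibly several samples; see
#'   [build_pileup()] / [simulate_pileup()]).
#' @param gene_models Gene-model data frame (see [read_gene_models()]), or
#'   `NULL` to treat every site as intergenic.
#' @param min_alt_reads Minimum alternate read count.
#' @param min_alt_frac Minimum alternate fraction of site depth.
#' @return Event data frame: `contig`, `pos`, `ref`, `alt`, `strand`,
#'   `gene_id`, `feature`, `conversion`, then `support_<s>`, `depth_<s>`,
#'   `freq_<s>` per sample (frequency is `NA` where that sample has no
#'   coverage).
#' @export
call_conversions <- function(pileup, gene_models = NULL, min_alt_reads = 2L,
                             min_alt_frac = 0.05) {
  if (min_alt_reads < 0 || min_alt_frac < 0)
    stop("thresholds must be >= 0")
  samples <- unique(pileup$sample)
  key <- paste(pileup$contig, pileup$pos)
  sites <- pileup[!duplicated(key), c("contig", "pos", "ref"), drop = FALSE]
  skey <- paste(sites$contig, sites$pos)
  ns <- nrow(sites)

  support <- depth <- list()
  for (s in samples) {
    sub <- pileup[pileup$sample == s, , drop = FALSE]
    m <- match(skey, paste(sub$contig, sub$pos))
    cnt <- matrix(0L, nrow = ns, ncol = 4L, dimnames = list(NULL, .BASES))
    dep <- numeric(ns)
    ok <- !is.na(m)
    cnt[ok, ] <- as.matrix(sub[m[ok], .BASES])
    dep[ok] <- sub$depth[m[ok]]
    support[[s]] <- cnt
    depth[[s]] <- dep
  }

  events <- list()
  for (b in .BASES) {
    cand <- sites$ref != b
    pass <- rep(FALSE, ns)
    for (s in samples) {
      sup <- support[[s]][, b]
      dep <- depth[[s]]
      pass <- pass | (cand & sup >= min_alt_reads & dep > 0 &
                        sup / dep >= min_alt_frac)
    }
    idx <- which(pass)
    if (!length(idx)) next
    ev <- sites[idx, , drop = FALSE]
    ev$alt <- b
    events[[b]] <- ev
  }
  if (!length(events)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      strand = character(0), gene_id = character(0),
                      feature = character(0), conversion = character(0),
                      stringsAsFactors = FALSE)
    for (s in samples) {
      out[[paste0("support_", s)]] <- integer(0)
      out[[paste0("depth_", s)]] <- integer(0)
      out[[paste0("freq_", s)]] <- numeric(0)
    }
    return(out)
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$contig, ev$pos, ev$alt), , drop = FALSE]
  rownames(ev) <- NULL

  fo <- .feature_at(ev$contig, ev$pos, gene_models)
  ev$strand <- fo$strand
  ev$gene_id <- fo$gene_id
  ev$feature <- fo$feature
  ev$conversion <- classify_conversion(ev$ref, ev$alt, ev$strand)

  ekey <- paste(ev$contig, ev$pos)
  for (s in samples) {
    m <- match(ekey, skey)
    sup <- support[[s]][cbind(m, match(ev$alt, .BASES))]
    dep <- depth[[s]][m]
    ev[[paste0("support_", s)]] <- sup
    ev[[paste0("depth_", s)]] <- dep
    ev[[paste0("freq_", s)]] <- ifelse(dep > 0, sup / dep, NA_real_)
  }
  ev
}

#' Filter events into editing candidates
#'
#' Removes events at known genomic-variant positions and events whose
#' alternate allele is carried by effectively all reads in every sample with
#' coverage: such variants are genomic polymorphisms, not editing.  The
#' "100%" rule uses `polymorphism_min_freq` (default 0.999) so that a single
#' sequencing-error read at high depth does not rescue a true polymorphism.
#' Samples without coverage at a site are ignored by the rule.
#'
#' @param events Event data frame from [call_conversions()].
#' @param known_snps Data frame with columns `contig` and `pos` of known
#'   genomic variants (VCF-like), or `NULL`.
#' @param polymorphism_min_freq Frequency treated as "100% of reads".
#' @return The surviving events (editing candidates), same columns.
#' @export
filter_candidates <- function(events, known_snps = NULL,
                              polymorphism_min_freq = 0.999) {
  if (!nrow(events)) return(events)
  drop <- rep(FALSE, nrow(events))
  if (!is.null(known_snps) && nrow(known_snps))
    drop <- drop | paste(events$contig, events$pos) %in%
      paste(known_snps$contig, known_snps$pos)
  freq_cols <- grep("^freq_", names(events), value = TRUE)
  fr <- as.matrix(events[, freq_cols, drop = FALSE])
  all_fixed <- apply(fr, 1L, function(f) {
    f <- f[!is.na(f)]
    length(f) > 0L && all(f >= polymorphism_min_freq)
  })
  out <- events[!(drop | all_fixed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conversion-type spectrum of a candidate set
#'
#' Counts sites and distinct genes per conversion type.  Percentages are
#' reported to integer precision, as conventional for conversion-spectrum
#' pie charts (e.g. 79 U-to-C sites among 590 total reports 13%).
#'
#' @param candidates Event/candidate data frame with columns `conversion`
#'   and `gene_id`.
#' @return Data frame with one row per conversion type (all 12, in canonical
#'   order): `conversion`, `n_sites`, `n_genes`, `pct`.
#' @export
spectrum_summary <- function(candidates) {
  total <- nrow(candidates)
  n_sites <- vapply(.CONVERSION_TYPES, function(ct)
    sum(candidates$conversion == ct), integer(1))
  n_genes <- vapply(.CONVERSION_TYPES, function(ct) {
    g <- candidates$gene_id[candidates$conversion == ct]
    length(unique(g[!is.na(g)]))
  }, integer(1))
  pct <- if (total) round(100 * n_sites / total) else rep(0, 12L)
  data.frame(conversion = .CONVERSION_TYPES, n_sites = unname(n_sites),
             n_genes = unname(n_genes), pct = unname(pct),
             stringsAsFactors = FALSE)
}

#' Read a known-variant list (VCF-like TSV)
#'
#' Minimal reader for a tab-separated variant list with at least `contig`
#' and `pos` columns (1-based).
#'
#' @param path TSV path.
#' @return Data frame with `contig` and `pos` (plus any further columns).
#' @export
read_known_snps <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("contig", "pos"), names(x))
  if (length(miss))
    stop("variant list lacks column(s): ", paste(miss, collapse = ", "))
  x
}
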