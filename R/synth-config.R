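# Configuration for the synthetic-data generators.

.FEATURES <- c("5'UTR", "CDS", "3'UTR")

#' Build an editing plan for the synthetic genome
#'
#' An editing plan lists the sites to plant in the synthetic reference: which
#' gene, which feature, the offset within that feature (1-based, counted in
#' transcript orientation), the transcript-level conversion to realise, and
#' the per-sample editing efficiencies (fractions of transcripts edited).
#'
#' @param gene Integer gene index (1-based, into the simulated gene set).
#' @param feature `"5'UTR"`, `"CDS"` or `"3'UTR"`.
#' @param offset 1-based offset of the site within the feature, counted in
#'   the direction of transcription.
#' @param conversion Conversion label, e.g. `"U-to-C"` (any spelling accepted
#'   by [normalize_conversion()]).
#' @param efficiency Named list or data frame with one numeric entry per
#'   sample, each in `[0, 1]`; e.g. `list(d12 = 0.77, d20 = 0.66)`.
#' @return A data frame with columns `gene`, `feature`, `offset`,
#'   `conversion` and `eff_<sample>` for each sample.
#' @export
#' @examples
#' editing_plan(gene = 1:2, feature = "3'UTR", offset = c(5, 10),
#'              conversion = "U-to-C",
#'              efficiency = list(d12 = c(0.3, 0.5), d20 = c(0.2, 0.4)))
editing_plan <- function(gene, feature, offset, conversion, efficiency) {
  plan <- data.frame(
    gene = as.integer(gene),
    feature = as.character(feature),
    offset = as.integer(offset),
    conversion = normalize_conversion(conversion),
    stringsAsFactors = FALSE
  )
  for (s in names(efficiency))
    plan[[paste0("eff_", s)]] <- as.numeric(efficiency[[s]])
  plan
}

#' Configuration of the synthetic sequencing study
#'
#' Collects every knob of the synthetic-data module: genome layout, coverage,
#' error rate, planted SNPs and editing sites, read geometry and the QC
#' contamination fractions.  The seed fully determines all generated outputs.
#'
#' The defaults emulate a two-timepoint seedling study: two samples
#' (`"d12"`, `"d20"`), planted editing efficiencies on the 20-80% scale,
#' a per-base substitution error around 0.1%, and genomic SNPs carried by
#' 100% of the reads in both samples.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param samples Character vector of sample names.
#' @param n_genes Number of genes on the synthetic contig.
#' @param gene_length,utr5_len,utr3_len Gene geometry in bases; the CDS takes
#'   the remainder, so `gene_length >= utr5_len + utr3_len + 3` is required.
#' @param intergenic_len Spacer length between (and flanking) genes.
#' @param coverage Mean reads per site (Poisson site-depth model).
#' @param error_rate Per-base substitution probability.
#' @param n_snp_sites Number of planted genomic SNPs (alternate allele on
#'   100% of reads in every sample).
#' @param editing_plan Data frame from [editing_plan()]; `NULL` for none.
#' @param read_length Read length in bases.
#' @param adapter_sequence Adapter used to contaminate (and later filter)
#'   reads.
#' @param adapter_fraction Probability a read carries the adapter.
#' @param n_fraction_high Probability a read is poly-N contaminated (15% of
#'   its bases replaced by N, i.e. above the 10% QC bound).
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         samples = c("d12", "d20"),
                         n_genes = 20L,
                         gene_length = 300L,
                         utr5_len = 60L,
                         utr3_len = 60L,
                         intergenic_len = 150L,
                         coverage = 50,
                         error_rate = 0.002,
                         n_snp_sites = 5L,
                         editing_plan = NULL,
                         read_length = 100L,
                         adapter_sequence = "AGATCGGAAGAGC",
                         adapter_fraction = 0,
                         n_fraction_high = 0) {
  cfg <- list(
    seed = as.integer(seed), samples = as.character(samples),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    intergenic_len = as.integer(intergenic_len),
    coverage = as.numeric(coverage), error_rate = as.numeric(error_rate),
    n_snp_sites = as.integer(n_snp_sites),
    editing_plan = editing_plan,
    read_length = as.integer(read_length),
    adapter_sequence = toupper(as.character(adapter_sequence)),
    adapter_fraction = as.numeric(adapter_fraction),
    n_fraction_high = as.numeric(n_fraction_high)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' @rdname synth_config
#' @param config A `synth_config` object to validate.
#' @export
validate_synth_config <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with(config, {
    if (n_genes < 0L) stop("invalid config: n_genes must be >= 0")
    if (n_genes > 0L && gene_length < utr5_len + utr3_len + 3L)
      stop("invalid config: gene_length must be >= utr5_len + utr3_len + 3")
    probs <- c(error_rate, adapter_fraction, n_fraction_high)
    if (any(probs < 0 | probs > 1))
      stop("invalid config: probabilities must lie in [0, 1]")
    if (read_length < 1L) stop("invalid config: read_length must be >= 1")
    if (anyDuplicated(samples)) stop("invalid config: duplicated sample names")
  })
  plan <- config$editing_plan
  if (!is.null(plan) && nrow(plan)) {
    eff_cols <- paste0("eff_", config$samples)
    need <- c("gene", "feature", "offset", "conversion", eff_cols)
    miss <- setdiff(need, names(plan))
    if (length(miss))
      stop("invalid config: editing_plan lacks column(s) ", paste(miss, collapse = ", "))
    if (!all(plan$feature %in% .FEATURES))
      stop("invalid config: editing_plan feature must be one of ",
           paste(.FEATURES, collapse = ", "))
    if (any(plan$gene < 1L | plan$gene > config$n_genes))
      stop("invalid config: editing_plan gene index out of range")
    lens <- c("5'UTR" = config$utr5_len, "CDS" = with(config, gene_length - utr5_len - utr3_len),
              "3'UTR" = config$utr3_len)
    if (any(plan$offset < 1L | plan$offset > lens[plan$feature]))
      stop("invalid config: editing_plan offset falls outside its feature")
    eff <- as.matrix(plan[, eff_cols, drop = FALSE])
    if (any(eff < 0 | eff > 1))
      stop("invalid config: efficiencies must lie in [0, 1]")
  }
  invisible(config)
}
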