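# Shared fixture builders: everything is generated in code under fixed seeds.

# A small two-sample study with two planted U-to-C sites and two SNPs.
small_config <- function(seed = 3L, ...) {
  plan <- editing_plan(gene = c(1L, 2L), feature = "3'UTR",
                       offset = c(10L, 5L), conversion = "U-to-C",
                       efficiency = list(d12 = c(0.4, 0.6),
                                         d20 = c(0.3, 0.5)))
  args <- list(
    seed = seed, n_genes = 4L, gene_length = 120L, utr5_len = 30L,
    utr3_len = 30L, intergenic_len = 60L, coverage = 30, error_rate = 0,
    n_snp_sites = 2L, editing_plan = plan, read_length = 60L
  )
  extra <- list(...)
  args[names(extra)] <- extra  # no recursive merge: editing_plan replaces
  do.call(synth_config, args)
}

# Quality string of a given Phred score.
qual_string <- function(phred, n) strrep(rawToChar(as.raw(phred + 33L)), n)

make_read <- function(seq, phred = 37L, id = "r1") {
  data.frame(id = id, seq = seq, qual = qual_string(phred, nchar(seq)),
             stringsAsFactors = FALSE)
}

# Flat-intensity trace: each channel constant over the whole scan range, with
# three called bases so the middle base has interior window boundaries.
flat_trace <- function(A = 0, C = 0, G = 0, T = 0, n_scans = 30L,
                       source = "cDNA") {
  chromatogram_trace(
    scans = data.frame(scan = seq_len(n_scans), A = A, C = C, G = G, T = T),
    basecalls = data.frame(base_index = 1:3,
                           scan_center = c(5, 15, 25),
                           called_base = c("A", "T", "A")),
    source = source, site_index = 2L
  )
}
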