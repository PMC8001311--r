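test_that("identical configurations give byte-identical genome files", {
  cfg <- small_config(seed = 11L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_reference(cfg)
    write_synth_genome(sim, file.path(d, "ref.fa"), file.path(d, "gm.tsv"),
                       file.path(d, "truth.tsv"))
    rd <- simulate_reads(sim, cfg)
    write_fastq(rd$reads$d12, file.path(d, "d12.fastq"))
  }
  for (f in c("ref.fa", "gm.tsv", "truth.tsv", "d12.fastq"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("a gene-free configuration yields empty annotation on a nonempty contig", {
  sim <- simulate_reference(synth_config(seed = 2L, n_genes = 0L,
                                         n_snp_sites = 0L))
  expect_identical(nrow(sim$gene_models), 0L)
  expect_gt(sum(Biostrings::width(sim$reference)), 0L)
})

test_that("gene geometry that cannot hold a CDS is rejected", {
  expect_error(synth_config(gene_length = 100L, utr5_len = 60L,
                            utr3_len = 60L), "invalid config")
})

test_that("planted sites land inside their declared feature on both strands", {
  plan <- editing_plan(gene = c(1L, 2L, 3L), feature = c("3'UTR", "3'UTR", "5'UTR"),
                      offset = c(10L, 10L, 1L), conversion = "U-to-C",
                      efficiency = list(d12 = 0.5, d20 = 0.5))
  cfg <- small_config(seed = 7L, editing_plan = plan, n_snp_sites = 0L)
  sim <- simulate_reference(cfg)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    iv <- sim$gene_models[sim$gene_models$gene_id == truth$gene_id[i] &
                            sim$gene_models$feature == truth$feature[i], ]
    expect_true(truth$pos[i] >= iv$start && truth$pos[i] <= iv$end)
  }
  # genomic base realises the transcript conversion on the gene's strand
  refb <- strsplit(as.character(sim$reference[[1]]), "")[[1]]
  expect_identical(refb[truth$pos],
                   uceditr:::.conversion_to_dna("U-to-C", truth$strand)$ref)
})

test_that("without editing or errors no alternate reads arise at non-SNP sites", {
  plan <- editing_plan(gene = 1L, feature = "3'UTR", offset = 10L,
                       conversion = "U-to-C",
                       efficiency = list(d12 = 0, d20 = 0))
  cfg <- small_config(seed = 5L, editing_plan = plan, error_rate = 0,
                      n_snp_sites = 1L)
  sim <- simulate_reference(cfg)
  rd <- simulate_reads(sim, cfg)
  for (s in cfg$samples) {
    aln <- place_reads(rd$reads[[s]], sim$reference)
    pu <- build_pileup(aln, rd$reads[[s]], sim$reference, sample = s)
    ref_count <- vapply(seq_len(nrow(pu)),
                        function(i) as.numeric(pu[[pu$ref[i]]][i]), numeric(1))
    nonref <- pu$depth - ref_count
    snp_pos <- sim$truth$pos[sim$truth$is_snp]
    expect_true(all(nonref[!(pu$pos %in% snp_pos)] == 0))
  }
})

test_that("alternate support at an edited site is binomial at the planted efficiency", {
  # one site at 29% efficiency, mean depth 2231: support concentrates near 647
  plan <- editing_plan(gene = 1L, feature = "CDS", offset = 20L,
                       conversion = "U-to-C",
                       efficiency = list(d12 = 0.29, d20 = 0.19))
  cfg <- small_config(seed = 17L, editing_plan = plan, coverage = 2231,
                      error_rate = 0, n_snp_sites = 0L)
  sim <- simulate_reference(cfg)
  pu <- simulate_pileup(sim, cfg)
  site <- pu[pu$pos == sim$truth$pos[1] & pu$sample == "d12", ]
  expect_lt(abs(site$C - 647), 3 * sqrt(2231 * 0.29 * 0.71))
})

test_that("SNP sites carry the alternate allele on every read in every sample", {
  cfg <- small_config(seed = 23L, n_snp_sites = 2L, error_rate = 0.001)
  sim <- simulate_reference(cfg)
  rd <- simulate_reads(sim, cfg)
  snps <- sim$truth[sim$truth$is_snp, ]
  for (s in cfg$samples) {
    aln <- place_reads(rd$reads[[s]], sim$reference)
    pu <- build_pileup(aln, rd$reads[[s]], sim$reference, sample = s)
    for (i in seq_len(nrow(snps))) {
      site <- pu[pu$pos == snps$pos[i], ]
      expect_identical(as.integer(site[[snps$alt[i]]]), as.integer(site$depth))
    }
  }
})

test_that("per-site counts conserve realized coverage", {
  cfg <- small_config(seed = 29L, error_rate = 0.01)
  sim <- simulate_reference(cfg)
  pu <- simulate_pileup(sim, cfg)
  expect_true(all(pu$A + pu$C + pu$G + pu$T + pu$N == pu$depth))
})

test_that("pileup-estimated frequencies recover planted efficiencies at depth", {
  ng <- 60L
  effs <- withr::with_seed(101L, runif(ng, 0.2, 0.8))
  plan <- editing_plan(gene = seq_len(ng), feature = "CDS", offset = 5L,
                       conversion = "U-to-C",
                       efficiency = list(d12 = effs, d20 = effs))
  cfg <- synth_config(seed = 31L, n_genes = ng, gene_length = 45L,
                      utr5_len = 15L, utr3_len = 15L, intergenic_len = 10L,
                      coverage = 1000, error_rate = 0, n_snp_sites = 0L,
                      editing_plan = plan)
  sim <- simulate_reference(cfg)
  pu <- simulate_pileup(sim, cfg)
  d12 <- pu[pu$sample == "d12", ]
  m <- match(sim$truth$pos, d12$pos)
  alt_count <- vapply(seq_along(m),
                      function(i) d12[[sim$truth$alt[i]]][m[i]], numeric(1))
  est <- alt_count / d12$depth[m]
  expect_gte(mean(abs(est - effs) < 0.05), 0.99)
})

test_that("trace pairs realise the planted efficiency and peak structure", {
  tp0 <- simulate_trace_pair(0, seed = 1L)
  expect_false(dual_peak(tp0$cdna, tp0$cdna$site_index))
  expect_false(dual_peak(tp0$gdna, tp0$gdna$site_index))

  tp <- simulate_trace_pair(0.773, seed = 2L)
  expect_equal(editing_efficiency(tp$cdna, tp$cdna$site_index, "C", "T"),
               77.3, tolerance = 1e-9)
  expect_false(dual_peak(tp$gdna, tp$gdna$site_index))

  tp5 <- simulate_trace_pair(0.5, seed = 3L)
  expect_equal(peak_area(tp5$cdna, tp5$cdna$site_index, "C"),
               peak_area(tp5$cdna, tp5$cdna$site_index, "T"),
               tolerance = 1e-9)
  expect_error(simulate_trace_pair(1.2), "efficiency")
})

test_that("trace generation is deterministic under a seed", {
  t1 <- simulate_trace_pair(0.3, noise_sd = 0.02, seed = 9L)
  t2 <- simulate_trace_pair(0.3, noise_sd = 0.02, seed = 9L)
  expect_identical(t1$cdna$scans, t2$cdna$scans)
})
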