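# Helper constructing a minimal multi-sample pileup row.
pileup_row <- function(pos, ref, sample, counts, contig = "chr1") {
  row <- data.frame(contig = contig, pos = pos, ref = ref, sample = sample,
                    A = 0L, C = 0L, G = 0L, T = 0L, N = 0L,
                    stringsAsFactors = FALSE)
  for (b in names(counts)) row[[b]] <- counts[[b]]
  row$depth <- row$A + row$C + row$G + row$T + row$N
  row
}

test_that("reads are placed at their unique minimum-mismatch position", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(
    withr::with_seed(1L, sample(c("A", "C", "G", "T"), 400L, replace = TRUE)),
    collapse = "")))
  sub <- substr(as.character(ref[[1]]), 101L, 150L)
  aln <- place_reads(data.frame(id = "exact", seq = sub), ref)
  expect_identical(aln$start, 101L)
  expect_identical(aln$mismatches, 0L)

  two_mm <- sub
  substr(two_mm, 5L, 5L) <- setdiff(c("A", "C"), substr(sub, 5L, 5L))[1]
  substr(two_mm, 40L, 40L) <- setdiff(c("G", "T"), substr(sub, 40L, 40L))[1]
  aln <- place_reads(data.frame(id = "mm2", seq = two_mm), ref)
  expect_identical(aln$start, 101L)
  expect_identical(aln$mismatches, 2L)

  three_mm <- two_mm
  substr(three_mm, 20L, 20L) <- setdiff(c("A", "G"), substr(sub, 20L, 20L))[1]
  aln <- place_reads(data.frame(id = "mm3", seq = three_mm), ref)
  expect_true(is.na(aln$start))
})

test_that("ambiguously placed reads are left unplaced", {
  core <- strrep("ACGTTGCAGT", 3L)
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "CCCCCCCCCC", core, "GGGGGGGGGG", core, "CCCCCCCCCC")))
  aln <- place_reads(data.frame(id = "dup", seq = core), ref)
  expect_true(is.na(aln$start))
  expect_error(place_reads(data.frame(id = "r", seq = "ACGT"),
                           Biostrings::DNAStringSet()), "empty")
})

test_that("a single read gives unit depth across its footprint and zero reads an empty stream", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(
    withr::with_seed(37L, sample(c("A", "C", "G", "T"), 200L, replace = TRUE)),
    collapse = "")))
  reads <- data.frame(id = "r1", seq = substr(as.character(ref[[1]]), 21L, 70L))
  aln <- place_reads(reads, ref)
  pu <- build_pileup(aln, reads, ref)
  expect_identical(pu$pos, 21:70)
  expect_true(all(pu$depth == 1L))
  expect_true(all(pu$A + pu$C + pu$G + pu$T + pu$N == 1L))
  empty <- build_pileup(aln[0, ], reads[0, ], ref)
  expect_identical(nrow(empty), 0L)
})

test_that("events carry per-sample support and frequency as in a worked example", {
  # 29% support (647 of 2231) in d12, 19% (240 of 1263) in d20, genomic T
  pu <- rbind(
    pileup_row(14198871, "T", "d12", list(T = 1584L, C = 647L)),
    pileup_row(14198871, "T", "d20", list(T = 1023L, C = 240L))
  )
  ev <- call_conversions(pu, gene_models = NULL)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$conversion, "U-to-C")
  expect_identical(ev$support_d12, 647L)
  expect_equal(ev$freq_d12, 0.29, tolerance = 1e-3)
  expect_equal(ev$freq_d20, 0.19, tolerance = 1e-3)
  expect_identical(ev$gene_id, NA_character_)  # intergenic default
  expect_identical(ev$strand, "+")
})

test_that("support and frequency floors both gate event emission", {
  one_read <- pileup_row(10L, "T", "d12", list(T = 99L, C = 1L))
  expect_identical(nrow(call_conversions(one_read, min_alt_reads = 2L)), 0L)
  low_frac <- pileup_row(10L, "T", "d12", list(T = 980L, C = 20L))
  expect_identical(nrow(call_conversions(low_frac, min_alt_frac = 0.05)), 0L)
  expect_identical(nrow(call_conversions(low_frac, min_alt_frac = 0.02)), 1L)
  all_ref <- pileup_row(10L, "T", "d12", list(T = 100L))
  expect_identical(nrow(call_conversions(all_ref)), 0L)
})

test_that("SNP and polymorphism filters drop fixed variants but keep partial ones", {
  pu <- rbind(
    pileup_row(100L, "T", "d12", list(T = 71L, C = 29L)),
    pileup_row(100L, "T", "d20", list(T = 81L, C = 19L)),
    pileup_row(200L, "G", "d12", list(A = 50L)),   # fixed in both samples
    pileup_row(200L, "G", "d20", list(A = 40L)),
    pileup_row(300L, "C", "d12", list(T = 60L)),   # fixed, listed SNP
    pileup_row(300L, "C", "d20", list(T = 55L)),
    pileup_row(400L, "A", "d12", list(G = 30L)),   # fixed where covered
    pileup_row(400L, "A", "d20", list())           # no coverage in d20
  )
  pu <- pu[pu$depth > 0, ]
  ev <- call_conversions(pu)
  expect_identical(nrow(ev), 4L)
  cand <- filter_candidates(ev, known_snps = data.frame(contig = "chr1",
                                                        pos = 300L))
  expect_identical(cand$pos, 100L)
  expect_equal(unname(cand$freq_d12), 0.29)
  # the filter never increases the event count
  expect_lte(nrow(cand), nrow(ev))
  expect_identical(nrow(filter_candidates(ev[0, ])), 0L)
})

test_that("one error read at high depth does not rescue a polymorphism", {
  pu <- rbind(
    pileup_row(50L, "T", "d12", list(C = 1999L, T = 1L)),
    pileup_row(50L, "T", "d20", list(C = 1500L))
  )
  ev <- call_conversions(pu)
  expect_identical(nrow(filter_candidates(ev)), 0L)
})

test_that("the conversion spectrum reports integer percentages over all 12 types", {
  cand <- data.frame(
    conversion = rep(c("U-to-C", "G-to-A"), c(79L, 511L)),
    gene_id = sprintf("G%03d", rep(1:59, 10L)),
    stringsAsFactors = FALSE
  )
  sp <- spectrum_summary(cand)
  expect_identical(nrow(sp), 12L)
  expect_identical(sp$n_sites[sp$conversion == "U-to-C"], 79L)
  expect_identical(sp$pct[sp$conversion == "U-to-C"], 13)
  expect_identical(sum(sp$n_sites), 590L)
  expect_true(abs(sum(sp$pct) - 100) <= 1)  # rounding slack

  empty <- spectrum_summary(cand[0, ])
  expect_true(all(empty$n_sites == 0L) && all(empty$pct == 0))
  single <- spectrum_summary(cand[cand$conversion == "U-to-C", ])
  expect_identical(single$pct[single$conversion == "U-to-C"], 100)
})

test_that("noiseless end-to-end recovery is perfect for edited sites and SNPs", {
  ng <- 40L
  effs <- withr::with_seed(53L, runif(ng, 0.05, 0.8))
  plan <- editing_plan(gene = seq_len(ng), feature = "3'UTR", offset = 8L,
                       conversion = "U-to-C",
                       efficiency = list(d12 = effs, d20 = effs))
  cfg <- synth_config(seed = 59L, n_genes = ng, gene_length = 45L,
                      utr5_len = 15L, utr3_len = 15L, intergenic_len = 10L,
                      coverage = 1000, error_rate = 0, n_snp_sites = 10L,
                      editing_plan = plan)
  sim <- simulate_reference(cfg)
  pu <- simulate_pileup(sim, cfg)
  ev <- call_conversions(pu, sim$gene_models)
  cand <- filter_candidates(ev)  # no blacklist: the 100% rule must suffice
  edited <- sim$truth[!sim$truth$is_snp, ]
  m <- match(edited$pos, cand$pos)
  expect_false(anyNA(m))                                   # sensitivity 1
  expect_identical(cand$conversion[m], edited$conversion)  # correct type
  expect_identical(cand$gene_id[m], edited$gene_id)
  snp_pos <- sim$truth$pos[sim$truth$is_snp]
  expect_false(any(cand$pos %in% snp_pos))                 # specificity 1
})
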