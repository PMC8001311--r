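test_that("peak areas integrate the channel over the call window", {
  tr <- flat_trace(C = 773, T = 227)
  # middle base window spans scans 10..20 (midpoints of calls at 5/15/25)
  expect_equal(peak_area(tr, 2L, "C"), 773 * 10)
  expect_equal(peak_area(tr, 2L, "G"), 0)
  # edge base windows are clipped at the trace boundary
  expect_equal(peak_area(tr, 1L, "C"), 773 * 9)   # scans 1..10
  expect_error(peak_area(tr, 9L, "C"), "base_index")
})

test_that("a Gaussian peak inside its window integrates to its analytic mass", {
  n <- 120L
  x <- seq_len(n)
  amp <- 500; ctr <- 60; sd <- 2
  g <- amp * exp(-(x - ctr)^2 / (2 * sd^2))
  tr <- chromatogram_trace(
    scans = data.frame(scan = x, A = g, C = 0, G = 0, T = 0),
    basecalls = data.frame(base_index = 1:3, scan_center = c(20, 60, 100),
                           called_base = c("C", "A", "C")),
    source = "cDNA", site_index = 2L)
  expect_equal(peak_area(tr, 2L, "A"), amp * sd * sqrt(2 * pi),
               tolerance = 1e-6)
})

test_that("editing efficiency is the two-channel peak-area ratio", {
  tr <- flat_trace(C = 773, T = 227)
  expect_equal(editing_efficiency(tr, 2L, "C", "T"), 77.3)
  expect_equal(editing_efficiency(flat_trace(T = 50), 2L, "C", "T"), 0)
  expect_equal(editing_efficiency(flat_trace(C = 5, T = 5), 2L, "C", "T"), 50)
  expect_error(editing_efficiency(flat_trace(), 2L, "C", "T"), "no signal")
  expect_error(editing_efficiency(tr, 2L, "C", "C"), "differ")
})

test_that("dual-peak detection compares secondary to primary area with >=", {
  expect_true(dual_peak(flat_trace(T = 100, C = 30), 2L, 0.1))
  expect_false(dual_peak(flat_trace(T = 100, C = 5), 2L, 0.1))
  expect_false(dual_peak(flat_trace(T = 100), 2L, 0.1))
  expect_true(dual_peak(flat_trace(T = 100, C = 10), 2L, 0.1))  # boundary
  expect_error(dual_peak(flat_trace(T = 1), 2L, 0), "secondary_min_frac")
})

test_that("efficiency and dual-peak calls are invariant to intensity scaling", {
  tp <- simulate_trace_pair(0.3, noise_sd = 0.01, seed = 13L)
  scaled <- tp$cdna
  scaled$scans[c("A", "C", "G", "T")] <- scaled$scans[c("A", "C", "G", "T")] * 37.5
  si <- tp$cdna$site_index
  expect_equal(editing_efficiency(scaled, si, "C", "T"),
               editing_efficiency(tp$cdna, si, "C", "T"), tolerance = 1e-12)
  expect_identical(dual_peak(scaled, si), dual_peak(tp$cdna, si))
})

test_that("noisy traces recover efficiency to within one percentage point on average", {
  f <- 0.42
  err <- vapply(1:100, function(s) {
    tp <- simulate_trace_pair(f, noise_sd = 0.02, seed = 1000L + s)
    abs(editing_efficiency(tp$cdna, tp$cdna$site_index, "C", "T") - 100 * f)
  }, numeric(1))
  expect_lt(mean(err), 1)
})

test_that("the confirmation rule demands a cDNA dual peak and a clean gDNA", {
  ctx <- "AATTGATAGGTTA"  # site base T at index 7, neighbours off-channel
  mk <- function(eff, gsf = 0) simulate_trace_pair(eff, context = ctx,
                                                   site_index = 7L,
                                                   gdna_secondary_frac = gsf)
  tp1 <- mk(0.773); tp2 <- mk(0.6574)
  v <- confirm_site(list(d12 = tp1$cdna, d20 = tp2$cdna), tp1$gdna)
  expect_true(v$confirmed)
  expect_equal(unname(v$efficiency_pct), c(77.3, 65.74), tolerance = 1e-6)

  t0 <- mk(0)
  v0 <- confirm_site(list(d12 = t0$cdna, d20 = t0$cdna), t0$gdna)
  expect_false(v0$confirmed)
  expect_identical(unname(v0$efficiency_pct), c(0, 0))

  # one edited sample suffices
  v1 <- confirm_site(list(d12 = t0$cdna, d20 = tp2$cdna), t0$gdna)
  expect_true(v1$confirmed)
  expect_identical(unname(v1$efficiency_pct[1]), 0)

  het <- mk(0.5, gsf = 0.5)
  vh <- confirm_site(list(d12 = het$cdna, d20 = het$cdna), het$gdna)
  expect_false(vh$confirmed)
  expect_identical(vh$note, "heterozygous-or-SNP")
})

test_that("traces round-trip through the columnar TSV format", {
  tp <- simulate_trace_pair(0.25, seed = 21L)
  sp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tp$cdna, sp, cp)
  back <- read_trace(sp, cp, source = "cDNA", site_index = tp$cdna$site_index)
  expect_equal(back$scans, tp$cdna$scans)
  expect_equal(back$basecalls, tp$cdna$basecalls)
  expect_equal(editing_efficiency(back, back$site_index, "C", "T"), 25,
               tolerance = 1e-9)
})

test_that("trace construction validates its inputs", {
  expect_error(chromatogram_trace(data.frame(scan = 1, A = -1, C = 0, G = 0, T = 0),
                                  data.frame(base_index = 1, scan_center = 1,
                                             called_base = "A")),
               "non-negative")
  expect_error(chromatogram_trace(data.frame(scan = 1:2, A = 0, C = 0, G = 0, T = 0),
                                  data.frame(base_index = 1:2,
                                             scan_center = c(2, 1),
                                             called_base = "A")),
               "increasing")
})
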