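# uceditr

Detection of candidate **U-to-C RNA editing sites** from RNA-seq-versus-
genome differences, and their confirmation by **Sanger chromatogram
dual-peak analysis** — as a tested, seedable R package.

U-to-C editing (amination of uridine to cytidine) shows up in RNA-seq as a
genomic T whose transcript reads carry a C. The hard part is telling
editing apart from genomic SNPs, sequencing errors and mapping artifacts.
`uceditr` implements the full inference chain:

* **read QC** — discard reads containing the adapter, more than 10% N
  bases, or more than 50% of bases under Phred 20 (`qc_filter()`,
  `qc_summary()`);
* **placement & pileup** — unique minimum-mismatch ungapped placement with
  at most 2 mismatches, then per-site base counts (`place_reads()`,
  `build_pileup()`);
* **conversion calling** — one event per site/alternate base with enough
  support, classified on the transcript strand into the 12 conversion
  types: genomic T-to-C on a `+` gene and A-to-G on a `-` gene are both
  transcript `U-to-C` (`call_conversions()`, `classify_conversion()`);
* **SNP/polymorphism filters** — drop known variants and sites whose
  alternate allele is carried by ~100% of reads in every covered sample
  (`filter_candidates()`);
* **annotation** — 5'UTR / CDS / 3'UTR / intergenic labels, UTR fraction,
  gene-list intersection (`annotate_feature()`, `utr_fraction()`,
  `intersect_gene_list()`);
* **chromatogram validation** — trapezoidal peak areas per call window,
  dual-peak detection, and the confirmation rule *dual peak in cDNA, single
  peak in gDNA*, with editing efficiency
  `100 * area(edited) / (area(edited) + area(unedited))`
  (`peak_area()`, `dual_peak()`, `confirm_site()`);
* **synthetic data with truth tables** — seeded reference/annotation/read/
  pileup/trace generators emulating a two-timepoint study, so every stage
  is exercisable and evaluable offline (`simulate_reference()`,
  `simulate_reads()`, `simulate_pileup()`, `simulate_trace_pair()`);
* **pipeline** — `run_pipeline()` ties the stages together from a YAML
  config; identical configs give byte-identical outputs. A thin CLI wrapper
  lives at `inst/scripts/uceditr-pipeline.R`.

Packaged under `inst/extdata/` are verbatim transcriptions of a published
56-row candidate-site ledger and 7-row validated-site ledger (with an
errata file recording their internal inconsistencies), a 10-gene PPR list,
and the demonstration pipeline config.

## Worked example

```r
library(uceditr)
res <- run_pipeline(uceditr_example("demo_config.yaml"), "demo-out")
#> [simulate] seed 42: 12 gene(s), coverage 40
#> [qc] d12: 2192/2366 reads kept
#> [place] d12: 2192/2192 reads placed
#> [qc] d20: 2102/2293 reads kept
#> [place] d20: 2102/2102 reads placed
#> [call] 11 event(s)
#> [filter] 7 candidate(s) after SNP/polymorphism filters
#> [validate] 7/7 candidate site(s) confirmed
res$validation
#>   contig position gene_id feature conversion confirmed note eff_d12 eff_d20
#> 1   chrS      701 GENE002   5'UTR     U-to-C      TRUE           77      66
#> 2   chrS      930 GENE003     CDS     U-to-C      TRUE           24       0
#> 3   chrS     1570 GENE005   5'UTR     U-to-C      TRUE            0      23
#> 4   chrS     1951 GENE006   3'UTR     U-to-C      TRUE           46      50
#> 5   chrS     2475 GENE007   3'UTR     U-to-C      TRUE            0      20
#> 6   chrS     3130 GENE009     CDS     C-to-U      TRUE           35      30
#> 7   chrS     3396 GENE010   3'UTR     U-to-C      TRUE           21       0
```

The demo config plants seven editing sites (plus four SNPs and contaminated
reads) on a 12-gene synthetic contig; the pipeline rediscovers exactly the
planted sites — the four SNPs are removed by the 100%-frequency rule — and
the noiseless trace assay returns each site's planted efficiency in
percent (`eff_d12`/`eff_d20`; a 0 means that sample showed no dual peak).

Single stages work standalone, e.g. reproducing a validated site's
efficiency from its chromatogram:

```r
tp <- simulate_trace_pair(0.773, seed = 7)        # 77.3% edited template
editing_efficiency(tp$cdna, tp$cdna$site_index, edited_base = "C",
                   unedited_base = "T")
#> [1] 77.3
dual_peak(tp$gdna, tp$gdna$site_index)            # clean genomic trace
#> [1] FALSE
```

See the vignette (`vignettes/u-to-c-editing-detection.Rmd`) for the model,
parameter rationale and limitations.

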