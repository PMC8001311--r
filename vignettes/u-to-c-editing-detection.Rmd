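---
title: "Detecting and validating U-to-C RNA editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating U-to-C RNA editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uceditr)
```

## The problem

RNA editing changes single bases of a transcript after transcription, so an
edited site appears in RNA-seq data as a reproducible mismatch between the
transcript base and the genomic reference. U-to-C editing (amination of a
uridine to cytidine) is the rare mirror image of the common plant C-to-U
deamination and, in nuclear transcripts of flowering plants, has long been
viewed with scepticism because an RNA-DNA difference alone cannot
distinguish editing from a genomic polymorphism, a sequencing error or a
mapping artifact.

`uceditr` implements the complete inference chain that makes such a claim
defensible:

1. **Clean reads.** Discard whole reads that contain the library adapter,
   more than 10% uncertain (N) bases, or more than 50% of bases below
   Phred 20.
2. **Placement and pileup.** Place clean reads at their unique
   minimum-mismatch ungapped position (at most 2 mismatches; ambiguous reads
   are dropped) and tally per-site base counts.
3. **Conversion calling.** Emit an event for every (site, alternate base)
   with sufficient read support, and classify it on the *transcript* strand
   into one of the 12 conversion types (`U-to-C`, `C-to-U`, ...).
4. **SNP and polymorphism filters.** Remove sites on a known-variant list
   and sites whose alternate allele is carried by effectively 100% of reads
   in every covered sample — those are DNA, not editing.
5. **Feature annotation.** Label each candidate with its gene feature
   (5'UTR, CDS, 3'UTR, intergenic); U-to-C candidates concentrate in UTRs.
6. **Chromatogram validation.** For each candidate, paired Sanger traces of
   cDNA and genomic DNA from the same material decide the call: a *dual
   peak* (edited C superposed on unedited T) in cDNA with a clean single
   peak in gDNA confirms editing; a dual peak in gDNA instead flags genomic
   heterozygosity. The per-sample editing efficiency is the edited-channel
   peak area over the sum of edited and unedited channel areas.

Because no raw sequencing from the motivating study is publicly deposited,
the package pairs every analysis stage with a seeded synthetic-data
generator plus truth tables, so the whole chain is exercised and evaluated
offline, and ships verbatim transcriptions of the study's candidate and
validation ledgers as fixtures.

## The estimators

**Pileup frequency.** At a site with realised depth $n$ and planted editing
efficiency $f$, the alternate read count is $\mathrm{Binomial}(n, f)$, so
the pileup estimate $\hat f = k/n$ has standard error
$\sqrt{f(1-f)/n}$; at depth 1000 the $3\sigma$ band is below 0.05 for all
$f$, which is the calibration the test-suite checks (over 200 planted sites,
at least 99% recover within 0.05).

**Conversion classification.** A genomic difference (ref, alt) on a gene on
strand $s$ maps to the transcript pair by complementing both bases when
$s = -$ and rewriting T as U. At fixed strand this is a bijection between
the 12 DNA pairs and the 12 transcript conversion types; the suite checks
all 24 cases against an independent complement-table oracle. Genomic T-to-C
on a plus-strand gene and A-to-G on a minus-strand gene are both transcript
`U-to-C`.

**Peak-area efficiency.** With channel areas $A_e$ (edited) and $A_u$
(unedited) over the assayed base's scan window,
$\mathrm{efficiency} = 100\, A_e / (A_e + A_u)$. Only the two relevant
channels enter; the ratio is invariant to overall intensity scaling. A dual
peak is declared when the second-largest channel area is at least 10% of
the largest (`secondary_min_frac`, exposed everywhere); 10% is a
conventional chromatogram heterozygosity cutoff, chosen because the source
material states no threshold.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis relies on:

* two timepoint samples (`d12`, `d20` by default; any number configurable),
* per-site binomial sampling of edited reads at planted efficiencies on the
  20–80% scale of the study's validated sites,
* an i.i.d. per-base substitution error channel (default 0.1–1% range,
  0.2%),
* genomic SNPs carried by 100% of reads in both samples,
* adapter- and poly-N-contaminated reads to exercise QC,
* cDNA/gDNA trace pairs with dual peaks only in cDNA (and heterozygous
  decoys with dual peaks in both).

Deliberate idealisations: reads are error-free apart from the substitution
channel (no indels — the target events are substitutions); qualities are
constant; coverage is Poisson per site (the study does not state its depth
distribution, so Poisson is this package's choice; the direct pileup
simulator draws sites independently); there is no splicing, so the
minimal placer is ungapped; traces are unit-amplitude Gaussians, one per
called base, on a 10-scans-per-base grid with peak standard deviation 1.5
scans. Passing tests therefore demonstrate correctness of the *inference
machinery* under the declared model, not robustness to real-library
artifacts such as strand bias, PCR duplicates or splice-junction
misalignment.

One numerical subtlety: generated trace contexts keep the two bases
adjacent to the assayed site off the edited/unedited channels. Otherwise the
Gaussian tail of a neighbouring same-channel peak bleeds about 0.02% of its
area into the site window and the noiseless peak-area ratio would recover
the planted efficiency only to ~0.03 percentage points instead of exactly
(to floating-point tolerance), which is the invariant the suite asserts.

## Parameters that matter

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `n_fraction_max` | 0.10 | `qc_params()` | discard read when N fraction strictly exceeds |
| `lowq_threshold` / `lowq_fraction_max` | 20 / 0.50 | `qc_params()` | low-quality base definition and tolerated fraction (strict) |
| `max_mismatch` | 2 | `place_reads()` | ungapped placement mismatch bound |
| `min_alt_reads` / `min_alt_frac` | 2 / 0.05 | `call_conversions()` | event emission floor; 2 keeps even weakly covered sites (the study examined sites with as few as 2 reads and found them rarely confirmable — raising the floor trades sensitivity for precision) |
| `polymorphism_min_freq` | 0.999 | `filter_candidates()` | "100% of reads" with tolerance for one error read at high depth |
| `secondary_min_frac` | 0.10 | `dual_peak()` | dual-peak area ratio cutoff |
| `noise_sd` | 0 | `simulate_trace_pair()` | trace noise as a fraction of peak amplitude; at 2% the mean efficiency-recovery error stays below 1 percentage point |

Coordinates are 1-based inclusive at every interface. Samples with zero
depth at a site are ignored by the polymorphism rule (their frequency is
undefined). Degenerate inputs fail loudly: empty references, efficiencies
outside [0, 1], both-channel-zero traces ("no signal"), malformed ledger
rows (reported with their line number).

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(uceditr_example("demo_config.yaml"), "demo-out")
res$validation
```

The packaged demonstration config plants seven editing sites (six U-to-C,
one C-to-U control) across features and strands of a 12-gene contig at
coverage 40, plus four SNPs and 8% contaminated reads. The run reports the
QC, placement, calling and filtering counts per stage, and the validation
table confirms exactly the planted sites with their planted efficiencies.
Two runs with the same config are byte-identical; problem sizes (a few kb of
contig, ~4,500 reads) keep the demonstration near-instant, while the
calibration experiments in the test-suite use the direct pileup simulator at
coverage 1000 over 200 genes.

## Known limitations

* The placer is exhaustive-complete only up to 2 mismatches (pigeonhole
  with three segments); it is a verification tool for synthetic data, not a
  competitor to a splice-aware aligner.
* Editing efficiency from a pileup and from a trace are both point
  estimates; no confidence intervals are attached.
* The polymorphism rule cannot rescue a genuinely 100%-edited site — by
  design, such a site is indistinguishable from DNA without the gDNA trace,
  which is exactly what the confirmation stage supplies.
* Multi-allelic sites are emitted as separate events per alternate base; no
  joint genotype model is fitted.
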