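# cnvreg

Discovery and characterization of copy number variable regions (CNVRs)
from population-scale, two-caller CNV call sets.

## What problem this solves

Whole-genome sequence surveys of copy number variation in livestock (and
other diploid populations) start from per-sample caller output: intervals
called as deletions (*loss*) or duplications (*gain*) in each animal.
Single-sample callers built on split reads and paired-end mapping give
precise breakpoints but high false-positive rates, so surveys combine
them with an orthogonal multi-sample read-depth caller and work at the
level of merged, population-wide regions. `cnvreg` implements that
workflow for anyone running or reanalysing such a survey:

1. **Consensus filtering** — keep a primary-caller call iff at least one
   single support-caller call from the same sample covers >= 10% of it
   (one-way overlap fraction, measured against the primary call).
2. **CNVR construction** — union overlapping same-type calls within each
   genome, then merge calls across samples into CNVRs as connected
   components under >= 50% *reciprocal* overlap
   (`min(o/len1, o/len2) >= 0.5`); type each region gain/loss/mixed;
   drop regions under 200 bp.
3. **Trio validation** — per parent-offspring trio, transmission rate
   (parent's CNVRs seen in the child / parent's CNVRs) and inheritance
   rate (child's CNVRs seen in either parent / child's CNVRs); the call
   error rate is estimated as `100% − mean inheritance` when de novo and
   somatic events are rare.
4. **Annotation & enrichment** — gene/QTL overlap at the >= 1 bp rule,
   breed-specific regions, cross-study comparison, Fisher's exact
   trait enrichment and binomial term overrepresentation, both
   Benjamini-Hochberg corrected.
5. **Synthetic data** — a pedigree-aware generator (three founder breeds,
   trios, sex-aware X/Y ploidy, two noisy callers with known truth) so
   the whole pipeline is testable without sequence data.

All tables are plain data.frames in BED/TSV dialects (0-based half-open
coordinates); GFF3 is converted on read.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated survey (60 animals, 12 trios, 300 CNV loci on a 20 Mb
three-chromosome genome, two imperfect callers). From the repository
root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consensus_and_cnvrs.R
Rscript analysis/03_summaries.R
Rscript analysis/04_trio_validation.R
Rscript analysis/05_annotation_enrichment.R
```

`02_consensus_and_cnvrs.R` prints the discovery narrative — how many
calls each caller emitted, how many survive consensus, and the final
region count by type:

```
Stage counts (discovery narrative):
  caller A calls     : 4984
  caller B calls     : 4979
  retained (consensus): 3997
  within-sample merged: 3986
  CNVRs (>= 200 bp)    : 309
  types: 17 gain / 292 loss / 0 mixed (sum 309)
```

Calls drop at the consensus step (caller-specific false positives and
coverage-dependent misses are unsupported), then collapse roughly 13:1
into population regions. `04_trio_validation.R` turns trio concordance
into an error estimate:

```
means: paternal 0.574, maternal 0.576, inheritance 0.863
estimated CNVR call error rate: 14%
```

Transmission means sit between the biological ideal of 0.5 and the
metric's ceiling of 1 (regions common to many carriers are "transmitted"
regardless of which haplotype the child drew), and the 14% error rate
reflects exactly the injected caller noise: with noise-free callers the
same pipeline yields inheritance 1.000 in all 12 trios and perfect
recall/precision against the planted truth (`evaluate_against_truth()`).

Equivalent calls in R, starting from files:

```r
library(cnvreg)
genome <- read_genome("results/sim/genome.tsv")
ped    <- read_pedigree("results/sim/pedigree.tsv")
a      <- read_calls("results/sim/calls_callerA.tsv", genome)
b      <- read_calls("results/sim/calls_callerB.tsv", genome)
thr    <- cnv_thresholds()        # 0.10 support, 0.50 reciprocal, 200 bp
cnvrs  <- filter_min_length(
  build_cnvrs(merge_within_samples(
    filter_supported_calls(a, b, thr, samples = ped$sample)), thr), thr)
trio_report(cnvrs, derive_trios(ped), samples = ped$sample)
```

`run_pipeline()` wraps the same sequence (plus summaries, annotation and
enrichment) into one call and returns an auditable report.

## Reference data

`inst/extdata/` ships small plain-text summary tables from a published
240-animal swine whole-genome CNV survey (per-chromosome CNVR
distribution, per-trio concordance rates, cross-study overlap counts,
and region type counts). They are inputs for the reproduction checks in
the test suite and the acceptance script; `cnvreg_extdata()` lists and
resolves them.

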