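---
title: "CNVR discovery from two-caller consensus: methods and design notes"
author: "cnvreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNVR discovery from two-caller consensus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvreg)
```

## The problem

Population-scale surveys of copy number variation (CNV) in livestock start
from per-sample caller output: for each sequenced animal, a list of genomic
intervals believed to be deleted (loss) or duplicated (gain) relative to
the reference. Individual-sample callers that combine split reads,
paired-end mapping and read depth give precise breakpoints but carry high
false-positive rates, so a survey typically (i) retains only calls
corroborated by an orthogonal multi-sample read-depth caller, (ii) merges
the surviving calls into population-level copy number variable regions
(CNVRs), and (iii) quantifies the residual error with parent-offspring
trios, before asking what genes and QTL the regions touch. `cnvreg`
implements that workflow end to end over plain BED/TSV tables, plus a
pedigree-aware generator of synthetic call sets so every stage can be
exercised against known truth.

## Coordinate conventions

All coordinates are 0-based half-open (`[start, end)`), the BED dialect
CNV callers emit; GFF3 input (1-based inclusive) is converted on read.
Half-open arithmetic is strict: intervals that merely touch
(`end == start`) share zero bases, never merge, and never count as a
feature overlap. Strand is ignored throughout — CNVs are unstranded.

## The pipeline model

**Consensus filtering.** A primary-caller call is retained when at least
one *single* support-caller call from the same sample covers at least a
fraction `support_frac` (default 0.10) of the primary call's length. The
fraction is one-way — shared bases divided by the *primary* call's length
— so a short support call inside a long primary call can still fail the
test. Three choices here were genuinely open and are worth stating:

* the threshold is inclusive (`>= 0.10`), reading "at least 10%" as the
  operative rule;
* support is evaluated against single calls, not the union of support
  coverage, so two 6% fragments do not add up to 12%;
* support must come from the same sample (both callers were run per
  sample; cross-sample support would conflate individuals), and call type
  need not agree unless `match_type = TRUE`, since a read-depth caller's
  loss/gain labels at low coverage are themselves noisy.

**Within-sample merging.** Before regions are formed, each genome's
overlapping same-type calls are unioned (>= 1 bp overlap). Different
types at one locus in one genome are biologically distinct events and are
left apart. Merged copy number is the length-weighted mean of members
when all are present.

**Cross-sample merging.** CNVRs are the connected components of the graph
whose vertices are calls and whose edges join pairs with reciprocal
overlap (the minimum of the two one-way fractions) at or above
`reciprocal_frac` (default 0.50). "Pairwise" could alternatively be read
as a clique requirement — every pair inside a region passing the
criterion. Component semantics was chosen because region growth is
transitive in the standard worked example (two staggered calls merge into
a region running from the leftmost start to the rightmost end) and
because components are independent of input order, which we assert under
randomized shuffles. Clique semantics remains available via
`build_cnvrs(..., semantics = "clique")` for sensitivity analysis; it is
greedy in coordinate order and therefore order-dependent by nature.

**Typing and length filtering.** A region is `gain` if all member calls
are gains, `loss` if all are losses, `mixed` otherwise; merging itself
ignores type, which is how mixed regions arise. Regions strictly shorter
than `min_cnvr_len` (default 200 bp) are removed — a region of exactly
200 bp survives, consistent with surveys whose smallest reported region
is just above the cutoff.

**Trio validation.** Transmission rate is the fraction of a parent's
CNVRs also called in the child; inheritance rate is the fraction of a
child's CNVRs called in at least one parent. "Called in" is evaluated at
CNVR-carrier level (the sample is a carrier of the population region),
matching the fact that validation happens after merging. Means across
trios are unweighted. The error rate is `1 - mean inheritance`, valid
when de novo and somatic events are rare relative to calling error; the
report states that assumption rather than hiding it. A trio whose
denominator sample carries no region yields `NA`, keeps its row, and is
excluded from means with a warning.

One wrinkle in reproducing published trio tables: averaging *printed*
(3-decimal) per-trio rates can differ in the third decimal from a mean
computed on unrounded rates, so our reproduction test compares the
inheritance mean at the table's printed resolution (+/- 0.001).

**Annotation and comparison.** Feature overlap uses the CNVR union span
and a 1 bp minimum. Cross-study comparison deliberately uses the loosest
rule (>= 1 shared base) and reports the overlapped count as a percentage
of this study's regions, printed with half-away-from-zero rounding at two
decimals — the convention such tables use; raw proportions are kept in
machine output. When checking a published comparison table we found two
rows whose printed percentages disagree with their own counts by one
unit in the last digit (1/3538 printed as 0.00% instead of 0.03%, and
8/3538 printed as 0.22% instead of 0.23%); these are documented printing
typos and are excluded from the exact reproduction check.

**Enrichment.** QTL trait enrichment contrasts, for each trait with at
least one CNVR-overlapped QTL record, that trait's records against all
other traits' records split by overlapped status, with a two-sided
Fisher's exact test (probability-mass rule, via `stats::fisher.test`) and
Benjamini-Hochberg correction across the tested traits. QTL are counted
as records, not deduplicated intervals. Term overrepresentation for gene
sets is the standard one-sided binomial test: `P(X >= k)` under
`Binomial(n, p0)` with `p0` the term's share of the gene universe; terms
with `k >= 1` form the correction family. The trait-vs-rest 2x2 is the
minimal construction consistent with published usage; a CNVR-level table
(regions as units) would be an alternative and is deliberately not
implemented. The universe for the binomial test is caller-supplied, since
annotated-gene versus whole-genome universes are a genuine modelling
choice.

## The synthetic generator

`sim_config()` describes a desk-scale analogue of a 240-animal,
three-breed swine survey: 48 founders split evenly across Duroc, Landrace
and Yorkshire, 12 trios whose children take breed "Composite" when the
parents' breeds differ, a 20 Mb genome (two autosomes and an X), and 300
CNV loci. Defaults were fixed once, from the study design being emulated
or from field-typical values, and are not tuned against test outcomes:

* locus lengths are log-normal with median 2.9 kb and mean 6.8 kb
  (`meanlog = log(2900)`, `sdlog = 1.3`), matching the characteristic
  right-skewed CNVR size spectrum; lengths are clamped to
  [250 bp, 400 kb];
* 5% of loci are gains — deletion-dominated call sets are the read-depth
  norm;
* per-breed allele frequencies are Beta(0.6, 3), giving the observed
  preponderance of rare regions (most carried by < 5% of samples);
* per-sample coverage is Gamma(3.2, rate 0.235) clamped to [1x, 31x],
  mean ~13.6x, mirroring a mixed low/high-coverage design;
* the false-negative probability is logistic in coverage,
  `fn_base + fn_range * plogis((8 - cov) / 3)`, calibrated so calls below
  5x are missed roughly twice as often as at 20x; boundary jitter is
  Gaussian (sd 100 bp); false positives arrive at 0.5 per Mb per caller
  per sample.

Genotypes are allele counts per locus: founders draw from their breed's
frequency with a slot per expected ploidy (autosomes 2; X 2/1 by sex; Y
0/1), and children draw one allele per parent Mendelianly — sons take no
paternal X, daughters receive the sire's X outright. Every non-founder
allele therefore traces to a parent allele, which the tests audit
directly. Loss calls on the male X are emitted at copy number 0.

`child_fp_prop` plants caller-concordant false positives on trio children
only, at a chosen proportion of their carried loci, away from all true
loci. Because both callers agree on them they survive consensus and
become child-only regions, so the expected inheritance rate is `1 - p` —
a clean parameter-recovery target (recovered to within 0.003 of 0.8 at
`p = 0.2` with 1,000 loci).

What the generator does *not* emulate: read-level signal (no FASTQ/BAM),
caller-specific artefact spectra (e.g. GC bias, segmental-duplication
pileups), overlapping true loci, de novo or somatic events, and linkage
between loci. Passing tests therefore demonstrate that the pipeline's
*logic* is correct under Mendelian inheritance and the stated noise
model, not that any particular real data set would yield a given error
rate.

## Numerical choices and degenerate inputs

* Percentages in printed tables use half-away-from-zero rounding at two
  decimals (base `round()` is half-to-even); raw proportions are retained
  alongside.
* Undefined rates (empty denominators) are `NA`, never 0; zero-variance
  correlations are `NA` with a warning; an odds ratio with an empty
  denominator margin reports `Inf` (or `NA` for 0/0), not an error.
* Locus placement is rejection sampling of non-overlapping intervals,
  largest first; an infeasible plan errors after a bounded number of
  tries rather than looping.
* All randomness flows from the single seed passed to
  `simulate_cnv_data()`; reruns are byte-identical.
* CNVR ids are `CNVR<zero-padded rank>` in (chromosome, start) order with
  natural chromosome ordering (numeric bodies, then X, then Y), so ids
  are deterministic across runs and platforms.

## Problem sizes

The default configuration (300 loci, 60 samples) runs the full pipeline
in a few seconds. The parameter-recovery experiment uses 1,000 loci on a
proportionally larger 80 Mb genome so that non-overlapping placement
stays comfortable at the same locus-length distribution. The null
enrichment control uses 200 replicates of a 400-record, 40-trait QTL
track with 30% of records overlapped at random; with no trait effect the
BH-significant fraction averages well below 0.05. The exhaustive Fisher
check enumerates every 2x2 table with all margins at most 15 against a
direct hypergeometric enumeration.

## Known limitations

* Carrier status is binary within a CNVR; integer copy-number genotyping
  per sample per region (and CNVR imputation) is out of scope.
* The consensus filter's complexity is quadratic per sample-chromosome
  group in the worst case; fine at survey scale, but a sorted sweep would
  be needed for calls in the tens of millions per group.
* Clique-semantics merging is greedy and order-dependent; it exists for
  sensitivity analysis, not as a primary mode.
* Breed-specificity is descriptive (single-breed carrier sets), not a
  formal breed-of-origin analysis.

## A worked run

```{r, eval = FALSE}
sim <- simulate_cnv_data(sim_config(), seed = 17)
thr <- cnv_thresholds()
retained <- filter_supported_calls(sim$calls_primary, sim$calls_support,
                                   thr, samples = sim$pedigree$sample)
cnvrs <- filter_min_length(build_cnvrs(merge_within_samples(retained)), thr)
trio_report(cnvrs, sim$trios, samples = sim$pedigree$sample)$mean_inheritance
evaluate_against_truth(cnvrs, sim)
```

The numbered drivers under `analysis/` run exactly this sequence against
files on disk and narrate each stage's counts.
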