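---
title: "Six-state LOH/CN integration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six-state LOH/CN integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnnloh)
```

# The problem

In tumors, loss of heterozygosity (LOH) can occur with a copy-number
(CN) deletion, with a gain, or — through mitotic recombination or
nondisjunction followed by reduplication — at normal copy number
(copy-number-neutral LOH, CNNLOH). CNNLOH is undetectable by CN
analysis alone: it needs paired genotypes. This package integrates the
two signals from matched tumor / adjacent-normal / blood trios assayed
on a dense SNP array, classifies every informative SNP into one of six
LOH-by-CN states, builds genomic segments, summarizes LOH burden per
case and per chromosome arm, and tests whether gene expression within
a CN class depends on LOH status.

# Procedure and assumptions

## LOH calling

LOH is observable only where the germline is heterozygous, so the
blood call defines informativeness: a SNP is informative in a case iff
blood = AB. At informative SNPs a homozygous tumor call is LOH, a
heterozygous one retention, and a NoCall undefined. This paired-
zygosity rule is the definitional core on which every downstream count
rests. Assumptions: genotypes are unphased and strandless (zygosity is
all that matters); the tumor is clonal enough that a real LOH event
flips essentially all its heterozygous SNPs. Opposite homozygotes
(blood AA, tumor BB) cannot arise from allele loss; they are counted
per case as a genotyping-error QC metric (`LohTrack` slot
`discordantHom`) and stay undefined. No smoothing or HMM is applied to
LOH calls: each stage stays auditable, and run-level cleanup happens at
segmentation.

## CN calling

Per-SNP intensity log2 ratios (tumor vs blood, or adjacent normal vs
blood) are smoothed with a centered boxcar window of `windowBp =`
100,000 bp — a window in base pairs, not SNP count, chosen to favor
extended regions over single-SNP noise — and each smoothed value is
assigned the CN state with the nearest expected center:

| state | copy number | center (log2 c/2) |
|------:|------------:|------------------:|
| 0 | 0 | −3.0 (floor) |
| 1 | 1 | −1.0 |
| 2 | 2 | 0.0 |
| 3 | 3 | 0.585 |
| 4 | 4 | 1.0 |

log2(0) is undefined, so state 0's center is set at −3 (~12% residual
signal, a typical array floor for homozygous deletions). Exact
midpoint ties break toward the diploid state 2 — the only deterministic
rule that never invents an aberration from a coin flip. The centers are
exposed as configuration (`stateCenters`) because a vendor tool's
internal thresholds are not public; nearest-center against the
theoretical means is the minimal faithful reading of "CN state"
semantics. States group as loss (≤ 1), neutral (2), gain (≥ 3); the
grouping, not the raw state, enters the six-state cross, matching how
the published tables pool CN 3 and 4.

## Six states and segmentation

At informative SNPs with a defined LOH call, the state is
LOH × {loss, neutral, gain}; everywhere else the LOH/CN state is
undefined (NA). A segment is a maximal run of equal-state SNPs that are
*consecutive among defined SNPs* on a chromosome, endpoints at the
first and last informative SNP of the run. The genuinely open design
question is what an undefined SNP between two same-state defined SNPs
does. We treat it as interstitial — it does not break the run — because
undefined loci carry no evidence of a state change, and uninformative
SNPs are described as lying *between* segments with undefined state.
The stricter reading is available as `breakOnUndefined = TRUE`. No
minimum segment size is imposed (`minSnps = 1`): per-SNP states, not
segments, feed the count tables, so the choice only affects segment
bookkeeping and gene mapping.

## Summary tables

Per-case and per-arm tables count defined LOH-positive SNPs split by
CN group (the retention analog counts LOH-negative SNPs). Display
fractions are rounded **half-up** to two decimals: base R's
round-half-even cannot reproduce the published footer counts, half-up
does. Footer statistics: the zero-fraction count uses the displayed
(rounded) fraction; range and median use unrounded fractions with
zero-total units contributing 0 (optionally excluded); the global
average is the pooled ratio Σcounts/Σtotals, not the mean of per-unit
fractions. "Percent of cases with LOH" is reported under both an
exact-zero and a rounded-zero rule because the published figures mix
the two (90%/93% match exact zeros, 50% matches rounded zeros).

Two cells of the packaged per-arm reference table contradicted their
own row totals and printed fractions (4q CN-gain, 22q CN-neutral); the
packaged fixture carries the values implied by each row's total and
printed fraction (1,058 and 3,334), and the tests assert the
recomputed statistics. Similarly, the published per-case medians
(0.00/0.60/0.13) do not recompute from the printed counts under any
zero-handling rule we tried (we obtain 0.01/0.62/0.15), so medians are
asserted at their recomputed values and excluded from the reproduction
headline numbers.

## Expression integration

Log2 fold change is tumor minus matched-normal log2 expression
(already RMA-normalized; normalization is consumed, not
re-implemented). A probe set in a case takes the state of the unique
segment that *fully contains* its reference region; partial overlap or
a gap means undefined for that case — containment is the conservative
mapping when a gene touches two states. Probe sets of one gene with
different reference regions are mapped and tested independently.

Within a CN class, probe sets with at least `minGroup = 2` cases per
LOH group are tested with a two-sided unpaired **pooled-variance**
t-test on log2 fold changes (Welch is a flag; pooled is the
historical default for this design and the group sizes are tiny).
Significance is raw P < `alpha` = 0.01 with no multiplicity correction
— the design reports the expected chance count ⌊n·α⌋ alongside instead
— and a BH-adjusted column is emitted for information only. The
reported t is positive when the LOH group is the lower one, matching
the sign convention of the published gene tables. Zero pooled variance
makes t undefined; such probe sets are flagged untestable and excluded
from significance counts rather than coerced. The "two-fold" flag is
defined on the LOH group's own tumor/normal fold change (≥ 2 or
≤ 0.5): in the published two-fold gene lists every LOH-group fold
change satisfies this while LOH/non-LOH ratios often do not, so that
is the rule the lists imply.

# The synthetic cohort

`simulateCohort()` emulates the study conditions: 30 trio cases, 17
with paired expression; germline heterozygosity 0.27; genotype call
rate 0.96 applied independently per tissue; mean probe spacing 5,800
bp with uniform jitter; per-SNP intensity noise sd 0.15. Planted
events use recurrent candidate regions per CN level — in real tumor
cohorts the same regions are hit in many cases, and recurrence is what
makes LOH-conditioned expression comparison possible — with inclusion
probabilities ordered like the published arm frequencies (CNNLOH most
recurrent, loss-LOH least) and LOH assigned per carried loss/gain
region with a coin weighted toward LOH. Within an LOH run the retained
allele is drawn once per run, not per SNP: per-SNP draws would create
impossible haplotype mosaics. Event copy numbers default to 1 (loss)
and 3 (gain); 0 and 4 are available through explicit event rosters.
Intensities are drawn Normal(log2(c/2), sd) with a −3 floor at c = 0;
expression pairs get per-gene baselines ~N(7, 1), fold-change noise sd
0.3, and a ±2 log2 shift for a designated 30% of genes when fully
inside a true LOH event.

What the simulator does **not** model — and what passing tests
therefore cannot show about real arrays: tumor purity and subclonality
(micro-dissection justifies a pure-tumor simulation; a purity knob is
deliberately out of scope), genotyping error inside calls (NoCall is
the only error mode), GC waves and probe-level intensity structure,
linkage disequilibrium between SNPs, and vendor normalization or
genotype-clustering internals. Recovery rates on simulated cohorts are
upper bounds for real data.

The default simulated genome is scaled down: 8 chromosomes of 12 Mb
(~16,500 SNPs), chosen so a full 30-case cohort simulates and analyzes
in seconds while windows, event sizes (25–50 expected informative
SNPs ≈ 0.5–1.1 Mb) and SNP densities stay at realistic scale. The
null-expression check uses 4,572 probe sets to match the size of the
published CN-neutral analysis; the power check uses 300 probe sets at
3 vs 14 cases.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally; BED export shifts to
  0-based half-open.
* Sliding windows are inclusive at both edges and never cross a
  chromosome; a chromosome with a single SNP keeps its raw value.
* Smoothing uses cumulative sums (exact, O(n) per case).
* Maps reject duplicate SNP ids, X/Y loci, and non-increasing
  positions; unsorted input is sorted with a warning.
* Recovery statistics count SNPs that received a state; NoCall-masked
  loci (4% by design) receive no call at all and are excluded from
  both numerator and denominator rather than counted as errors.
* Genotype matrices missing map SNPs are completed with NC under a
  warning; unknown tokens are hard errors.
* All simulator randomness derives per-stage from one root seed;
  identical configurations are byte-identical, and stages can be
  re-run in isolation.

# Known limitations

* The CN caller is a boxcar-plus-nearest-center classifier, not a
  reimplementation of any vendor algorithm; only the window size and
  the state alphabet are shared by construction.
* LOH calls carry no error model; a single miscalled genotype can
  split a segment (mitigated by, but not corrected for, the undefined-
  interstitial rule).
* Arm assignment comes from the SNP map, not a cytoband file;
  acrocentric p-arms exist only if the map says so.
* The expression test treats cases as independent and fold changes as
  normal within groups; with group sizes of 2 the t-test is valid but
  weak, which is precisely why the expected-false-positive count is
  reported alongside.
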