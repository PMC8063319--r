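---
title: "Pool-seq divergence scans and the calibration of local-score outliers"
author: "poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq divergence scans and the calibration of local-score outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pooled whole-genome sequencing (pool-seq) estimates population allele
frequencies from a single sequencing library per population: at each site
the reads act as a binomial sample of the pool's allele frequency, with the
read depth playing the role of sample size.  Given three populations — two
focal forms and a geographically distant outgroup — the scan asks which
genomic regions are unusually differentiated, and, critically, how often a
scan of this design would flag regions on data that evolved with *no*
selection at all.

`poolscan` implements the full path: sync-format ingestion, SNP retention
rules, window statistics, single-SNP outlier tests with a kinship
correction, a Lindley-process local score with Monte-Carlo chromosome-wide
thresholds, a neutral Wright–Fisher simulator used to measure the scan's
false-positive rate, and an exact hypergeometric gene-set enrichment for
genes in high-FST windows.

## Data model and retention rules

Input is the PoPoolation2-style sync table: per site and pool six counts
(A:T:C:G:N:del).  A site is retained as a SNP when it

1. has exactly two alleles (bases with nonzero pooled counts; N/del never
   count as alleles),
2. has global minor-allele frequency > 0.05, computed from read counts
   summed over all pools,
3. shows at least 2 pooled copies of the minor allele (sequencing-error
   guard), and
4. has per-pool depth within [15, 50] in *every* pool (low depths make
   frequency estimates unstable; high depths indicate collapsed paralogs).

Optional exclusion intervals (e.g. around indels) drop sites outright.
Filtering is idempotent, and all downstream estimators consume the per-pool
minor-allele counts, depths and frequencies of the retained SNPs.

## Window statistics

Read depth is used as a haploid sample size — standard pool-seq practice;
the finite number of chromosomes in the pool (160 per population here) is
ignored, which slightly understates sampling variance but affects all
populations equally.

* **FST, Weir–Cockerham:** the two-level haploid (allele-count) estimator.
  Per SNP the among- and within-population variance components `a` and `b`
  are computed from depths and frequencies; a window's estimate is
  `sum(a) / sum(a + b)` over its SNPs (ratio of sums).  Negative per-SNP
  estimates are legitimate (e.g. `-1/(n̄-1)` at identical intermediate
  frequencies).  Windows are non-overlapping 100 kb tiles; window `k` spans
  `[(k-1)·10^5 + 1, k·10^5]`; windows with fewer than 10 SNPs
  (configurable) report `NA`.  The genome-wide value is the unweighted mean
  of window estimates; a ratio-of-sums alternative is one line of code away
  and both are reported by the analysis scripts where relevant.
* **FST, Karlsson:** the two-pool estimator used by PoPoolation2's
  `--karlsson` mode, likewise aggregated as a ratio of sums.  Bit-for-bit
  agreement with PoPoolation2 is not claimed (that tool applies its own
  coverage rescaling); rank agreement with Weir–Cockerham is a tested
  property (Spearman ρ > 0.95 on simulated windows).
* **π and dxy:** per variant site `π̂ = n/(n-1) · 2p̂(1-p̂)` and
  `d̂xy = p̂₁(1-p̂₂) + p̂₂(1-p̂₁)`; window values divide the per-site sums by
  the number of covered sites (all window bp by default — exact for the
  simulator, where depth never leaves the retention bounds; a coverage
  mask can be supplied for real data).  Note `dxy(p,p) = 2p(1-p)` exactly,
  which is what makes the π-vs-dxy contrast informative where FST is driven
  by diversity loss rather than divergence.
* **Bins:** windows are grouped by strict thresholds FST > 0.2/0.3/0.4/0.5;
  per bin the median π and dxy and the percent decrease
  `100·(1 - bin/genome-wide)` are reported.

## FLK, LK and the local score

Per SNP, the **LK** statistic standardizes the multi-population
Weir–Cockerham estimate by the genome-wide mean:
`T_LK = (r-1)·θ̂_ℓ / mean(θ̂)` (negative estimates clamped to zero), referred
to χ² with `r-1` df.  **FLK** replaces the implicit "equal drift in every
population" assumption with a kinship matrix `F`: pairwise Reynolds
distances `D = -ln(1-θ̂)` are computed by two-pool Weir–Cockerham over all
SNPs, the rooted three-taxon tree follows from the three-point formulas
with the root at the node joining the outgroup, and `F` is the diagonal
matrix of root-to-tip branch lengths (in a rooted 3-taxon star no pair of
tested populations shares drift).  Using branch lengths directly as
variance scales is a mild-drift approximation: the coancestry
parameterization would be `1 - exp(-branch)`, identical to first order.
Per SNP the ancestral frequency is the GLS estimate
`p̂₀ = (1'F⁻¹p̂)/(1'F⁻¹1)` and
`T_FLK = (p̂-p̂₀1)' V⁻¹ (p̂-p̂₀1)` with `V = F·p̂₀(1-p̂₀)`, χ² with `n-1` df.
SNPs whose estimated ancestral frequency is 0 or 1 carry no drift
information and are dropped.  Under ideal conditions (true star kinship,
exact frequencies, weak drift) `T_FLK` is χ²₂ to numerical accuracy — a
tested property against genuine Wright–Fisher drift.

The **local score** turns per-SNP evidence into regions: with scores
`s_i = -log10(p_i) - ξ`, the Lindley track is
`h_i = max(0, h_{i-1} + s_i)`; maximal runs with `h > 0` are excursions,
and an excursion is significant when its peak reaches the chromosome's
threshold.  Choices that matter:

* `ξ` is the 85% empirical quantile of the `-log10 p` distribution,
  computed genome-wide per statistic (a per-chromosome mode exists behind
  an argument).  `ξ` must lie between the mean and the maximum of that
  distribution; if the quantile falls below the mean it is raised to the
  mean with a warning.
* The chromosome-wide threshold is Monte-Carlo: `B` resamples (with
  replacement) of the chromosome's own `-log10 p` values, each of the
  chromosome's length, and the threshold is the `1-α` quantile of the `B`
  track maxima (`α = 0.05`, `B = 200` in the analysis scripts, 500 by
  default).  This preserves the stated contract — under independent
  p-values an `α` fraction of chromosomes exceeds its own threshold
  (a tested property; note the check must be self-referential: a threshold
  resampled from one chromosome is systematically too low for *fresh*
  chromosomes, because fresh extremes beyond the observed maximum cannot
  be resampled) — while letting linkage produce any inflation actually
  present in the data.
* Regions span their full excursion (first SNP with `h > 0` through the
  last before the track returns to zero); the peak is the first argmax.

## The neutral simulator

The simulator is an individual-based forward Wright–Fisher model written in
C++: an ancestral population of `N` diploids starts with no variation and
evolves `t_burn` generations; it then splits into three isolated demes of
`N` diploids for `t_split` further generations.  Transmission draws
Poisson(`rL`) crossovers and Poisson(`µL`) infinite-sites mutations per
gamete (a new mutation redraws any occupied position; no back-mutation).
Pool sequencing draws, independently per site and deme, an integer depth
from a rounded truncated normal (mean 23, sd 5, bounds [15, 50] applied
after rounding) and a Binomial(depth, frequency) read count; per-site
depths reflect the coverage variation of real pool-seq rather than a
per-chromosome depth.  The pooled-count MAF > 0.05 filter is applied before
output.  All randomness flows from `(seed, chromosome index)`: identical
configurations re-create byte-identical sync files.

The full-scale design — `N = 1000`, 1000 + 2500 generations, 75 Mb
chromosomes, `µ = 2×10⁻⁷`, `r = 1.5×10⁻⁸`, 30 chromosomes per pseudo-genome
— is configurable but not desk-size.  `scale_config()` divides `N` and all
generation counts by λ and multiplies `µ` and `r` by λ, preserving `4Nµ`,
`4Nr` and `t/2N`; a tested invariance property confirms that λ ∈ {5, 10}
leaves heterozygosity and FST unchanged within Monte-Carlo error.  The desk
profile (`desk_config()`) uses λ = 10 with 2 Mb chromosomes; at that size
the 20-pseudo-genome false-positive study runs in roughly a quarter hour on
one CPU, which is the problem size used by the tests and the acceptance
script.  Things the generator deliberately does not emulate: selection,
migration, sequencing error, PCR duplicates and indels — so passing tests
speak to estimator correctness and calibration under neutral drift with
linkage, not to robustness against those artefacts.

## What the false-positive study shows

Running the scan on strictly neutral pseudo-genomes measures how often the
local score calls regions where nothing but drift and linkage is present
(`fpr_experiment()`; per-chromosome FPR = significant regions /
genomes × chromosomes, so values above 100% are possible when chromosomes
carry several excursions).  Two findings from this package's own runs are
worth stating plainly:

* The realized differentiation of the simulated design is high: mean
  pairwise 100-kb-window Weir–Cockerham FST ≈ 0.57 at the end of the
  neutral history (`t/2N = 1.25` of isolated drift predicts Hudson-style
  FST ≈ 0.5 analytically, before the MAF filter's upward pull).  At that
  drift level the FLK χ² tail saturates — a fixed difference cannot yield a
  p-value below ~0.03 when branch lengths are ~0.43 — so the `-log10 p`
  distribution is bounded and strongly non-uniform.
* With saturated, linked p-values the iid-resampled thresholds are
  overwhelmed: the scan calls tens of regions per 30-chromosome neutral
  pseudo-genome (FPR above 100%), and the count grows with chromosome
  length.  Destroying linkage by permuting SNP order (keeping the p-value
  marginal) collapses the count to the nominal handful — the inflation is
  entirely linkage-driven.  The qualitative conclusion — the local score's
  real type-I error under linked neutral data far exceeds the nominal
  chromosome-wide `α`, so its region calls on real data should not be
  trusted without a matched neutral calibration — is the study's robust
  message, and the package reproduces it at every scale tried.

## Numerical and design choices

* Window index: `floor((pos-1)/w) + 1`; sync positions 1-based; window
  bounds inclusive.  Bin membership strict (`>`).
* Minor allele: smaller pooled count, ties broken by A:T:C:G order.
* Top-window table: `k = round(valid·fraction)`, at least 1; ties by FST
  descending, then chrom, then start.
* Degenerate inputs: monomorphic sites yield zero FST components and
  undefined estimates (components still pool into windows); empty bins give
  `NA` medians; an all-zero score track yields threshold 0 and no calls.
* LK's mean-θ̂ normalization uses clamped estimates over SNPs where the
  estimate is defined.
* Enrichment: the exact two-set hypergeometric upper tail (the mode the
  study design actually exercises), with the sampling universe always
  containing the target; `include`/`exclude` state whether the supplied
  background already contains the target genes, and the two coincide for a
  disjoint background.  BH q-values are reported for convenience; the
  significance gate is raw p ≤ 0.001.  No GO-graph propagation: the
  gene-to-term map is taken as given.
* There is no separate command-line wrapper: the numbered drivers under
  `analysis/` (simulate → windows → outlier scan → FPR study → enrichment)
  are the workflow entry points, each a thin script over exported
  functions.

## Known limitations

* Depth as haploid sample size ignores the finite pool (no NPStat-style
  correction); π is therefore a depth-corrected, not pool-size-corrected,
  estimator.
* The Monte-Carlo threshold treats SNPs as exchangeable within a
  chromosome; it makes no attempt to model autocorrelation analytically.
  That is intentional — the inflation under linkage is the measurement —
  but it means thresholds should not be reused across datasets.
* The kinship tree is the rooted three-taxon case; more populations would
  need a general tree-fitting step.
* The enrichment module tests a flat term map; ranked-list (mHG) testing
  and term-graph propagation are out of scope.
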