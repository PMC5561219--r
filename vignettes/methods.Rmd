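---
title: "Methods: scanning for convergent and divergent selection between two domestication centers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for convergent and divergent selection between two domestication centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Pigs were domesticated at least twice, in China and in Europe, each
time from the local wild boar. Comparing the two wild/domestic pairs
(CHW/CHD and EUW/EUD) lets us separate three signatures that a single
pair cannot distinguish:

* regions selected in **both** centers toward the **same** haplotypes
  (*unidirectional* or convergent selection);
* regions selected toward **opposite** haplotypes
  (*bidirectional* or divergent selection);
* and, with one ancient European domestic genome (AP) predating modern
  Asian gene flow into European breeds, whether a shared selected
  haplotype was selected in Europe **before** or **after** it
  introgressed from Asia.

`duosweep` implements this scan as a set of composable tibble-first
functions plus one orchestrating pipeline.

# The scan, stage by stage

## Windowed Weir–Cockerham F~ST~ and ZF~ST~

Per site we compute the two-population variance components *a*, *b*,
*c* of Weir & Cockerham (1984) from observed genotype counts
(`site_fst_components()`), excluding uncalled individuals from the
per-population sample sizes. Window F~ST~ over a 20-kb window sliding
in 10-kb steps is the ratio of sums Σa / Σ(a+b+c) across sites — the
"weighted" convention of vcftools. Three numerical conventions matter:

* **negative window values are retained** (not clamped at 0); clamping
  would distort the genome-wide Z null;
* windows with fewer than `min_snps` variants (default 10) are flagged
  `low_snp` and excluded from the Z-transformation, so noise-driven
  outliers cannot become candidates;
* a window whose assessed sites are all monomorphic in the pooled pair
  has a 0/0 component ratio; we report it as F~ST~ = 0 rather than
  undefined, because zero variation is zero differentiation. This
  matters at near-fixed shared sweeps, exactly the windows the
  unidirectional test needs in its Z pool.

ZF~ST~ is `(x - mean) / sd` over all retained windows of a contrast
genome-wide (not per contig), with the sample (n−1) standard
deviation. Candidate windows use the strict threshold ZF~ST~ > 2.

## Regions, sharing, and the permutation filter

Candidate windows are merged into maximal overlapping-or-book-ended
runs per scan; the regions of the CHD and EUD scans that intersect by
at least 1 bp become *common* regions (extent = intersection).

Each common region is tested by label permutation: within each
contrast's sample pool (CHD+CHW; EUD+EUW) group labels are shuffled
with sizes held fixed, the region's ratio-of-sums F~ST~ is recomputed,
and an empirical p-value is formed as p = (n + 1)/(n~perm~ + 1) with
n~perm~ = 1000 by default, so the smallest attainable p is 1/1001.

**Which permutations count?** We expose two rules. The default,
`max`, computes a per-contrast empirical p and reports the maximum —
the standard valid test of the intersection hypothesis "the region is
differentiated in *both* contrasts": it rejects at level α only if
both marginal tests do. The alternative `joint` rule counts a
permutation only when it exceeds the observed F~ST~ in both contrasts
simultaneously. Although intuitively strict, under an exchangeable
null the joint p behaves like the product of two independent uniforms,
whose CDF at 0.01 is 0.01(1 − ln 0.01) ≈ 0.056 — i.e. it is
anticonservative if compared to a nominal per-region level, which our
calibration tests on exchangeable simulated regions confirm. `max` is
therefore the default; regions pass at p < 0.01.

## The unidirectional / bidirectional split

Within permutation-passing common regions, the CHD-vs-EUD ZF~ST~
separates convergent from divergent selection. The region-level value
is the length-weighted mean of *member* windows — windows with more
than half their span inside the region extent (with a fallback to any
overlapping window for extents narrower than half a window). Limiting
the summary to member windows is deliberate: flanking windows that
mostly cover unselected sequence otherwise dilute a clean 20-kb sweep
toward the genome mean and wash out the split.

A region is called **unidirectional** iff region ZF~ST~ < −1, and
**bidirectional** iff region ZF~ST~ > 2, in both cases additionally
requiring the haplotype filter H12~CHD~ > H12~CHW~ and
H12~EUD~ > H12~EUW~ (strict inequalities throughout, ties fail).
Regions with a missing H12 summary are flagged and stay `common`.

## H12

H12 = (p₁ + p₂)² + Σ~i>2~ p~i~² over the sorted haplotype class
frequencies in a window of 50 consecutive SNPs advancing by 10 SNPs;
pooling the top two classes makes the statistic sensitive to soft as
well as hard sweeps. Haplotype classes are exact allele-string matches
(internally keyed as base-2 integers for windows of ≤ 52 sites, which
is exact in doubles); haplotypes with any missing call in a window are
dropped rather than imputed, to avoid fabricating identity. Phased
input is required — unphased calls raise an error rather than a
silently wrong spectrum.

Because H12 rises mechanically as sample size falls, a larger domestic
group is compared to its wild counterpart via subsampling: `reps = 10`
random draws of the wild group's size (whole individuals, both
haplotypes), averaged per window. The region summary is the maximum
over windows whose center SNP lies inside the region — max preserves
the sweep peak that the filter is looking for.

## Ancient-genome identity scores

Per site, each group's REF-allele frequency is assessed only if at
least half of the group's individuals are fully called (for the
single-individual ancient genome this means the site itself must be
called). IS = 1 − |F₁ − F₂| per assessed site, averaged per window;
region IS is the unweighted mean over overlapping windows. For each
unidirectional region:

* IS~AP,CHD~ < IS~AP,EUW~ + 0.1 → `introgression_then_selection`
* IS~AP,CHD~ > IS~AP,EUW~ + 0.1 → `pre_introgression_selection`
* equality at the margin → `ambiguous`; any undefined IS (e.g. no
  ancient coverage in the region) → `no_data`.

The 0.1 margin absorbs the baseline similarity difference between the
comparisons; equality exactly at the margin is deliberately not forced
into either class.

## Tajima's D, ΔAF, IBD

ΔAF is the windowed mean per-site |allele-frequency difference|.
Tajima's D uses the standard 1989 constants; with missing data each
site is restricted to its called alleles and the sample size entering
the constants is the floor of the window's mean per-site called count
(the estimator needs one n; the floor of the mean is the conservative
integerization). S = 0 windows are undefined, flagged rather than
raised.

The IBD proxy calls a haplotype pair IBD in a 20-kb bin iff ≥ 99% of
co-called sites agree (≥ 5 shared sites), concatenating adjacent IBD
bins into segments; nIBD per bin is the fraction of cross-group
haplotype pairs whose segments cover the bin,
nIBD = cIBD / (2n₁·2n₂). This proxy is **not** an HMM IBD caller;
`nibd()` accepts externally produced segment tables so output from a
dedicated caller can be consumed instead.

# The simulator

`simulate_cohort()` is the package's test substrate, not an afterthought.
Each 20-kb block carries K = 16 founder haplotypes whose
100 SNP alleles are drawn to be polymorphic among founders. An
ancestral founder-frequency vector (symmetric Dirichlet) drifts along
each branch of the population tree
(ancestor → {CHW, EUW} → {CHD, EUD}) through the Dirichlet analogue of
the Balding–Nichols reparameterization,
f′ ~ Dir(f(1−θ)/θ), with θ = 0.25 per wild branch and 0.03 per
domestication branch. Genotypes are formed by random pairing of
founder draws (monoecious random mating); the single ancient sample
draws from the EUW pool (or from the swept EUD pool in the
pre-introgression scenario) and is masked at 30% of sites by default.
All randomness flows through per-block seeds derived from the master
seed, so identical configurations are byte-identical regardless of
evaluation order.

Scenario semantics: `uni_introgression` and `uni_preintrogression`
raise one CHW-origin founder to frequency 0.98 in both CHD and EUD and
differ only in the ancient sample's source pool; `bidirectional`
raises two distinct founders in CHD and EUD respectively; `neutral`
regions drift only.

Free parameters the underlying study does not pin down were set once,
on realism grounds, and are exposed in `sim_config()`:

* **wild–wild divergence** θ = 0.25 per branch reproduces the deep
  Eurasian wild boar split (genome-wide CHW-vs-EUW F~ST~ around
  0.3–0.4 in published resequencing panels) and, importantly, gives
  the windowed CHD-vs-EUD F~ST~ distribution the structure seen on
  real data — mean ≈ sd ≈ 0.2, so that near-identical regions sit
  near ZF~ST~ = −1 and near-fixed divergent regions well above +2.
  With a much smaller θ the between-block drift variance dominates
  (coefficient of variation > 1) and the bimodal split cannot exist
  for any caller.
* **K = 16 founders per block** approximates the tens of distinct
  haplotypes real 20-kb windows harbor; fewer founders again inflate
  between-block variance.
* **the favoured founder** is standing variation at low frequency
  (closest to 0.05) in its source wild pool and penalized for presence
  in the opposite wild pool: a domestication allele that matched the
  Eurasian wild consensus would produce no detectable differentiation,
  and an "Asian-origin" haplotype common in European wild boar would
  contradict the introgression narrative the ancient-genome test
  relies on.
* **sweep truth blocks are mutually non-adjacent** (≥ 1 insulating
  block): adjacent sweeps would merge into a single candidate region
  and could not be scored per region; real selected regions are
  megabases apart.

What the simulator does **not** emulate: recombination within blocks,
mutation (haplotypes are exact founder copies, so fully swept windows
can be literally monomorphic — see the F~ST~ = 0 convention above),
linkage between blocks, realistic demography (bottlenecks, expansion),
or sex chromosomes. Passing recovery tests on this substrate therefore
demonstrates the *logic* of the scan — thresholds, merging,
classification, calibration — not its power on real genomes, which
depends on demography and recombination the simulator deliberately
omits.

# Problem sizes and defaults

The default simulated study is 2 contigs × 2 Mb (400 scan windows,
~20,000 SNPs), 30 samples per core group plus one ancient genome,
10 truth regions per sweep scenario and 50 neutral regions, sweep
frequency 0.98, ancient missingness 0.3. Permutations default to 1000
per region (p resolution 1/1001); H12 subsampling uses 10 replicates.
These sizes keep a full pipeline run around half a minute on one core
while leaving every stage's signal comfortably above its threshold;
calibration experiments use 200 exchangeable neutral regions
(domestic drift θ = 0, so domestic and wild samples are genuinely
exchangeable within each contrast pool).

# Known limitations

* The scan is SNP-based and biallelic-only; indels and multiallelic
  records are skipped at input.
* The bimodal CHD-vs-EUD structure presupposes comparable divergence
  between the two centers; with very asymmetric histories the fixed
  −1/+2 cutoffs would need re-deriving from the observed Z
  distribution.
* The IBD proxy trades sensitivity for transparency; for publication
  analyses feed `nibd()` segments from a dedicated caller.
* The DEG proximity enrichment uses a plain Pearson chi-squared on the
  2×2 table (no continuity correction, matching common practice for
  large gene sets); for small tables pass `correct = TRUE`.
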