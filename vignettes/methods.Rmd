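---
title: "Methods: selection scans and constrained ordination in selscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and constrained ordination in selscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`selscape` implements a landscape-genomics workflow for diploid populations
sampled along environmental gradients: genotype-level quality control,
windowed selection scans (Weir–Cockerham $F_{ST}$ and XP-EHH) with empirical
rank significance, genotype PCA, and partial redundancy analysis (RDA) for
genotype–environment and genotype–phenotype association. Because suitable
whole-genome panels with known selective history do not exist at desk scale,
the package ships a first-class simulator whose ground truth (differentiation
level, sweep locations, cline loci, QTL effects) is recorded alongside the
data, so every analytical layer can be validated by parameter recovery.

# The synthetic-population generator

## Sampling design

`simConfig()`/`simulateMetadata()` lay out a hierarchical design of
`nGradients` environmental gradients, each crossed with elevation-defined
agroecologies — lowland (400–1800 m.a.s.l.), midaltitude (1800–2400) and
highland (2400–3500), the conventional East-African classification — with
`popsPerCell` village-level populations per cell. Defaults (4 gradients × 3
agroecologies × 2 populations × 18 diploids) mirror the scale of
gradient-design village-chicken studies (roughly two dozen populations of
15–20 birds each). Each population receives one elevation drawn uniformly
inside its band, one geographic coordinate, and one environmental profile;
samples inherit their population's values because such designs record a
single coordinate per village.

Six environmental predictors (two precipitation quarters, May solar
radiation, elevation, soil clay content, temperature seasonality) are
generated from a conditional multivariate normal given the standardized
elevation, so that their full 6×6 correlation matrix — including each
predictor's correlation with elevation — matches a configurable target
(`envCor`). The default target encodes the usual covariation of tropical
highland climates (precipitation rising, radiation and seasonality falling
with elevation, all at |r| ≤ 0.5 so the default design is not degenerate for
predictor reduction). A non-positive-semi-definite target is rejected.

## Haplotypes

`simulateHaplotypes()` builds phased haplotypes in three steps:

1. **Ancestral frequencies** $p \sim \mathrm{Uniform}(0.05, 0.95)$ per SNP.
2. **Per-population target frequencies** from the Balding–Nichols model,
   $q_k \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$,
   whose variance is exactly $F\,p(1-p)$; $F$ (`fstLevel`, default 0.02 — the
   scale of between-gradient differentiation in village chicken) is the
   differentiation parameter recovered by the $F_{ST}$ scans. $F=0$
   degenerates to identical frequencies across demes.
3. **Founder-mosaic haplotypes with frequency resampling.** Each haplotype is
   a mosaic of `founderHaplotypes` templates, switching template between
   adjacent SNPs with probability $1-(1-r)^{d}$ for gap $d$ bp
   (`recombRate`, default $10^{-6}$ per bp — a cumulative, since-founding
   switch rate, not a per-meiosis rate; it sets the LD decay scale to tens
   to hundreds of kb). Within each population the ALT count at every site is
   then drawn $\mathrm{Binomial}(2N, q_k)$ and met by flipping as few
   haplotype entries as possible (current carriers keep their allele), so
   site-level differentiation and haplotype-scale LD coexist. The flips act
   like scattered mutations and are what makes neutral EHH decay.

The per-population target frequencies, sweep and cline registries are stored
in the panel's metadata; `writeFixture()` serializes them as JSON so recovery
analyses never re-derive the truth. Setting `freqResample = FALSE` exposes
the raw mosaic stage (used to verify the degenerate case `recombRate = 0`,
where every haplotype equals a founder template).

## Injected signals and traits

* `injectSweep()` emulates a recent hard sweep: a fraction
  (`carrierFraction`) of the target populations' haplotypes is replaced by
  copies of one donor haplotype across a span centered on the core,
  forcing EHH ≈ 1 over the span. Loci outside the span and non-target
  populations are untouched (asserted as a locality invariant).
* `injectEnvCline()` rewrites a single locus so each population's ALT
  frequency is $\mathrm{logistic}(\mathrm{logit}(q_0) + \beta z)$ in the
  standardized predictor $z$ — the signal class detected by RDA.
* `simulateTraits()` builds each quantitative trait as an additive QTL sum
  plus a linear environmental term plus Gaussian noise, exactly linear by
  construction so zero-noise cases are testable identities.

## What the generator does *not* emulate

No coalescent genealogy, mutation-rate realism, pedigree or sex chromosomes;
recombination is a homogeneous mosaic process, and frequency resampling
perturbs haplotypes minimally rather than through generations of drift.
Passing recovery tests therefore demonstrates that the estimators detect the
intended signal classes at realistic effect sizes and sample sizes — not
that they are robust to demographic confounding absent from the generator.

# Quality control

`filterVariants()` applies, in a fixed order on each filter's survivors:
call rate < 0.7, then minor allele frequency < 0.05, then Hardy–Weinberg
exact p < 5×10⁻⁶ (all strict inequalities; a variant at exactly the
threshold survives). The HWE test is the standard exact conditional test
(sum of probabilities of heterozygote configurations no more probable than
the observed one; not mid-p), computed from log-factorials and verified
against exhaustive enumeration. Phred-quality and indel-proximity filters
operate on variant-calling evidence that does not exist in this package's
inputs and are assumed applied upstream.

`ldPrune()` scans sliding windows of 100 variants stepping by 10; within a
window every pair with $r^2 > 0.5$ (squared Pearson correlation of dosages,
pairwise-complete, defined as 0 under zero variance) loses its lower-MAF
member, ties dropping the later position; passes repeat until stable. The
removal rule is fixed for determinism rather than to match any specific
tool's internal tie-break. Missing genotypes are excluded pairwise here and
in allele counts; they are mean-imputed only inside ordination.

# Selection scans

## Windowed $F_{ST}$

Per-site Weir–Cockerham (1984) two-population variance components $a, b, c$
give $\theta = a/(a+b+c)$; sites monomorphic across both groups are excluded
(not zeroed) so window means are not diluted. Windows are 50 kb with 25-kb
step; the window statistic is the arithmetic mean of defined per-site
$\theta$ ("average $F_{ST}$"), with the ratio-of-sums
$\sum a / \sum(a+b+c)$ emitted alongside as `stat_ratio`. The two differ
systematically: on Balding–Nichols data at $F = 0.10$ the mean-of-ratios
sits near 0.08 while the ratio-of-sums recovers ≈ 0.10 (mean-of-ratios is
the contract used in tests because the windowed statistic is defined as an
average).

## EHH, iHH, XP-EHH

EHH at a flanking site is the probability that two random carrier
haplotypes are identical from the core to that site,
$\sum_k \binom{n_k}{2} / \binom{n}{2}$; the outward scan stops once EHH
drops below 0.05 (that point is recorded and included in the integral) or
at the chromosome end. iHH is the trapezoidal integral of the curve over
physical bp, both directions summed. These inner scans are compiled (Rcpp)
since they dominate runtime.

The per-site XP-EHH score is $\ln(\mathrm{iHH}_A / \mathrm{iHH}_B)$ using a
population-level iHH that combines both core alleles weighted by allele
count (so sites monomorphic in one population remain defined), standardized
genome-wide — not within frequency bins — which keeps the statistic exactly
antisymmetric under population swap. Cores require pooled MAF ≥ 0.05. The
cutoff, MAF floor and genome-wide standardization are the conventional
defaults of the haplotype-scan ecosystem, recorded as arguments.

## Empirical significance and overlap

Windows are ranked per method; the empirical p is rank divided by the
number of windows with a defined statistic (one-sided descending for
$F_{ST}$; separate descending/ascending tails for XP-EHH, reported as
signed $-\log_{10} p$). Ties share the worst rank of their block, so a
fully tied scan is never significant. A window is flagged when
$p \le$ `topFrac` (default 0.01): the boundary is included so that, with
distinct values, exactly $\lfloor 0.01 N \rfloor$ windows are retained —
"the top 1%". Cross-method overlap is reported with all three defensible
denominators (union, $F_{ST}$ set, XP-EHH set) because a single "percent
overlap" is ambiguous.

`layeredScan()` expands the three analytical layers into pairwise
contrasts: by gradient (layer I), by agroecology pooled over all gradients
except one with a distinct evolutionary history (layer II, default
exclusion "II"), and by agroecology within that gradient alone (layer III).

# Ordination and association

`pcaGenotypes()` uses Patterson normalization (center by $2\hat p$, scale
by $\sqrt{\hat p(1-\hat p)}$, mean-impute first, drop monomorphic SNPs) and
eigendecomposes the sample covariance $XX^\top/m$.

`partialRda()` follows the textbook constrained-ordination algebra:
mean-impute and center the dosage response (no variance scaling — the
ordination convention for allele counts, switchable), residualize response
and predictors on `[1, Z]` by least squares, fit the multivariate
regression, and take the SVD of the fitted values; eigenvalue $k$ is
$d_k^2/(n-1)$ and site scores are the projections $U d$. SNP loadings are
correlations between residualized dosages and axis scores. $R^2$ is the
fitted fraction of conditioned variance; adjusted $R^2$ uses Ezekiel's
formula with the conditioning degrees of freedom removed (undefined when
$n \le p + q + 1$). Significance comes from a permutation pseudo-F with 999
seeded row permutations of the residualized predictors, each re-residualized
on the conditioning space before refitting (the reduced-model convention;
without that re-projection null p-values are anti-conservative), with the
add-one correction. Collinear predictor columns are dropped via QR rank and
reported; with full-rank predictors the number of constrained axes equals
the number of predictors.

Candidate SNPs are loadings beyond 3.5 SD from the axis mean (two-tailed
normal rate ≈ 5×10⁻⁴) on any of the first three axes — the union counts
each SNP once on its most extreme axis; the scree inspection behind "three
axes" is replaced by the explicit `nAxes` argument. Each outlier is
assigned to the predictor with maximal |r| against its residualized dosage
(ties resolve by predictor order; correlations are computed on the
residualized variables, matching the partial model), binned into
(0,0.3], (0.3,0.4], (0.4,0.5], (0.5,0.6], (0.6,1]. Geography conditioning
is longitude + latitude; elevation is deliberately a predictor, not a
conditioning variable. `geaPipeline()` composes reduction (|r| > 0.7,
strict; a forced-keep list mirrors the convention of retaining a
biologically motivated trait pair slightly above threshold) → partial RDA →
outliers → assignment, and exports a Manhattan table of
$-\log_{10}$ two-tailed normal tail probabilities of the most extreme
standardized loading.

# Annotation and enrichment

Windows map to genes by ≥ 1 bp intersection of 1-based inclusive intervals
(BED input is converted from 0-based half-open by rtracklayer). Enrichment
is an upper-tail hypergeometric test per user-supplied gene set against a
universe defaulting to all annotated genes, with Benjamini–Hochberg control
and significance at q < 0.1 — a generic re-implementation that deliberately
carries no pathway-database dependency.

# Numerical choices and degenerate inputs

* Strict inequalities at every QC threshold; boundary cases are tested.
* $\theta$ may be negative (moment estimator); monomorphic-in-both sites are
  NA and excluded from window means; windows without informative SNPs are
  excluded from ranking.
* XP-EHH scores are undefined where either population's iHH is 0 or
  undefined; a zero standard deviation of raw scores (identical populations)
  standardizes to 0.
* Zero loading SD on an axis yields no outliers from that axis;
  zero-variance residualized dosages are reported unassigned.
* All generators restore the caller's RNG state and are reproducible from
  seeds; changing the seed changes the output.

# Problem sizes used in the tests

The validation suite scales the study design down to desk size as the
package's own choice of test conditions: unit fixtures use 2 populations ×
10 diploids × 400 SNPs on 2 Mb; parameter-recovery experiments use
2 × 100 diploids × 20,000 SNPs on 2 × 10 Mb for the $F = 0.10$ recovery,
2 × 25 diploids × 32,000 SNPs on 8 × 10 Mb for sweep recovery (a 500-kb
sweep spans ~21 overlapping windows, so the genome must hold enough windows
for a 1% retention to contain them — trivially true at full genome scale),
and 36 populations × 14 diploids × 2,000 SNPs for cline recovery; null
calibration uses 200 fits at $n = 60$ with 199 permutations plus one
20,000-SNP null RDA. The end-to-end pipeline test runs a reduced
4-gradient design.

# Known limitations

* The simulator's LD model has a single global decay scale; real genomes
  mix hotspots, structural variants and variable recombination.
* Empirical rank p-values are relative by construction: some windows are
  always "significant" even under a global null; they calibrate retention,
  not error rates.
* Genome-wide (bin-free) XP-EHH standardization can over- or under-weight
  frequency classes relative to binned variants of the statistic.
* The hypergeometric enrichment treats gene sets as exchangeable and
  ignores gene length and LD clustering of candidates.
* Window→gene mapping intersects the full window, not the top SNP, so long
  genes accumulate windows.
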