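---
title: "Models and methods behind mppgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mppgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`mppgwas` implements a comparative association pipeline for quantitative
traits measured on structured multi-parent maize populations: a nested
set of recombinant inbred line (RIL) families sharing one common parent,
together with BC1 backcross subsets and a partial diallel of F1 hybrids
among the founders. The focal trait throughout is kernel row number
(KRN), an integer-scored, highly heritable, predominantly additive ear
trait; nothing in the code is specific to KRN beyond defaults on the
"rows" scale (trait mean near 15).

Because the entries descend from few founders through known crosses,
linkage disequilibrium is extensive and family structure is strong. The
pipeline therefore (i) controls structure with fixed population and
subpopulation effects rather than a kinship matrix within the mapping
populations, (ii) conditions the single-variant scan on QTL detected by
joint linkage analysis, and (iii) thins dense association results into a
non-redundant candidate set before any cross-population validation.

## Phenotype adjustment (BLUEs)

Replicated records are reduced to one adjusted value per entry with the
two-factor mixed model

y_ij = entry_i (fixed) + group_j (random) + e_ij,

where the grouping factor is the trial for multi-environment RIL data or
the replication for single-season derived populations. Only one variance
ratio lambda = sigma^2_group / sigma^2_error needs estimating, so REML is
solved by a bounded one-dimensional profile search; because the entry
incidence matrix has orthogonal columns and the grouping factor has few
levels, every solve reduces to a diagonal matrix plus a low-rank
(Woodbury) correction. With a single grouping level, or fewer than two
residual degrees of freedom, BLUEs fall back to entry means. This direct
solver was chosen over general mixed-model machinery because the model
never has more than one variance ratio, and a dense fixed-effect design
with thousands of entry columns would be needlessly expensive.

## Joint QTL analysis

A two-step composite interval mapping (CIM) procedure supplies the QTL
used both as covariates of the single-variant model and as regions for
thinning:

1. **Cofactor selection.** Forward stepwise regression on a sparse
   linkage-marker grid (the variant nearest each 1-cM map position; real
   linkage analyses run on genetic-map markers, not the full variant
   set), adding the best marker by partial F while its inclusion p-value
   is below 0.05, capped at 10 cofactors.
2. **Scan.** Marker regression on a 1-Mb grid, at each position testing
   the nearest linkage marker and conditioning on the design effects and
   all cofactors outside the exclusion window. The window is genetic
   (10 cM) when a map is available: a physical window in a
   recombinationally cold region would leave near-perfectly linked
   cofactors in the model and shield true peaks. LOD =
   (n/2) log10(RSS_reduced / RSS_full).
3. **Threshold.** The 95th percentile of the genome-wide maximum LOD over
   phenotype permutations (1,000 by default; tests use 100–200). The
   permutation shuffles within subpopulation strata so the null preserves
   the family structure that the fixed effects model.
4. **Peaks and intervals.** Local maxima above threshold (peaks within
   one grid step merge to the higher) with 1.5-LOD support intervals.
   On map-marker scans the interval endpoints are expanded outward to
   the flanking scan positions, the standard convention of linkage
   mapping; at the very high LOD values this design produces, the raw
   interpolated drop can be narrower than the peak-location sampling
   error, and dense-variant profiles under near-perfect LD are
   noise-jagged, which is why the scan itself runs on map markers.

## The three association models

All three models include fixed population and subpopulation effects; no
kinship correction is applied within the mapping populations.

**Single-variant (SV) scan.** For variant k on chromosome c, OLS of the
BLUE on intercept + population + subpopulation + the QTL peak markers on
chromosomes other than c + dosage_k, with a two-sided partial-F test of
the dosage effect. Entries missing dosage_k are dropped for that variant
only; QTL covariates are mean-imputed so the covariate set is constant.

**Stepwise regression (STR).** Forward selection by smallest partial-F
p-value with backward elimination after every addition (any retained
marker whose final-model p rises to alpha is removed). Stops at no
qualifying candidate, cumulative R^2 >= 0.8 (computed on the sum of
squares remaining after the fixed effects), or 300 markers — the
classical stopping options of stepwise GWAS implementations. Missing
dosages are mean-imputed so every step uses one entry set. Per marker
the package records the p-value at first entry, the final-model p-value
(used for thinning by default, since the ambiguity between the two is
real) and the incremental R^2 at entry.

**Bayesian multi-variant (BMV, BayesC).** All variants are fitted
simultaneously: effect c_k is 0 with prior probability pi and
N(0, sigma^2_c) otherwise, with a common effect variance. A single-site
Gibbs sampler (C++ core, genome-order sweeps, single chain, R RNG for
reproducibility) samples fixed effects from flat-prior conditionals,
inclusion indicators with the effect marginalized, effects from their
conditional normals, and both variances from scaled-inverse-chi-square
conditionals (prior df 4, scale set so the prior mean equals the
configured variance). The per-marker model frequency (MF) is the
fraction of post-burn-in samples including the marker. Training is
two-step: a short chain (1,000 sweeps, 100 burn-in) under unit prior
variances, then a long chain (41,000 / 1,000 by default) with priors
replaced by step-1 posterior means. pi is a fixed hyperparameter
(BayesC, not BayesC-pi); the default 1 - 100/M targets roughly 100
markers in the model, and the pipeline uses 1 - 20/M at desk scale so
the null inclusion rate sits well below the 0.02 MF threshold. The
marker-effect prior variance derives from the genetic variance as
sigma^2_c = genVar / (sum_k 2 p_k (1 - p_k) (1 - pi)), the standard
genomic-prediction parameterization. With pi = 0 and frozen variances
(df -> infinity) the posterior mean equals ridge regression, which the
tests exploit as a closed-form oracle.

## Thinning, binning and the validation set

Dense results from linked populations concentrate significance in a few
regions, so candidate (KAV) sets are thinned: inside each QTL support
interval ±1 Mb the 10 most significant variants are kept; outside,
variants passing the model threshold (-log10 p > 20 for SV, MF > 0.02
for BMV, inclusion p < 0.05 for STR) are grouped per chromosome so that
no within-group pairwise distance exceeds 10 Mb (complete linkage, built
greedily seeding each group with the best remaining score — the exact
grouping algorithm is otherwise underdetermined, so this deterministic
construction is fixed and covered by enumerated fixtures), and the top
10 per group are kept. Ties at any cap resolve to the lower (chrom,
pos). Selected variants map to half-open 100-kb bins
(floor((pos-1)/1e5)); the validation set is every variant in a bin
detected by >= 2 models plus, per model, the top-scoring private bins
(20 by default) contributing up to 2 variants each. Private-bin ranking
uses each model's own score scale; no cross-model normalization is
attempted. Negative-control variants are drawn from clearly
non-associated variants (SV p > 0.5) and pass through the identical
validation code path.

## Genetic validation

Three unrelated population types are emulated and tested:

* **Inbred panel** (elite-line-like): derived from the founder pool by
  generations of random mating plus selfing, so it shares ancestral
  haplotype blocks but none of the family structure. Tested with a
  per-variant kinship mixed model — variance ratio estimated once on the
  null model via the spectral decomposition of the VanRaden genomic
  relationship matrix built from background SNPs, then per-variant GLS
  Wald tests (with K = I this reduces exactly to OLS) — and with a naive
  OLS test without structure control.
* **Pooled heterogeneous accessions**: accession allele frequencies
  follow a Balding–Nichols model around the founder-pool frequencies;
  pools of up to 12 plants estimate each accession's frequency; a
  one-sided Welch t-test asks whether the trait-increasing allele (sign
  taken from the discovery GWAS) is more frequent in high-trait than
  low-trait pools. A quasibinomial GLM alternative sits behind a switch.
* **Divergently selected population**: 30 cycles of truncation selection
  on an ear-length-like primary trait genetically correlated with the
  focal trait (default r = -0.6, built by pleiotropy plus an independent
  polygenic component), two arms (long/short), Wright–Fisher
  reproduction among Ne selected parents. Observed frequency differences
  between the arms are tested against a neutral drift null simulated at
  the same Ne and generations; empirical p-values carry the +1
  correction so they are never zero, making them slightly conservative
  (super-uniform) by construction.

Benjamini–Hochberg FDR at q < 0.05 is applied within each population's
informative candidates (call rate > 0.4, MAF > 0.05, strict
inequalities); a variant is validated when it passes in at least one
population, in the GWAS-consistent direction where the test defines one
(pooled and selection tests). Summaries report rates per discovery model
and model combination, the share of between-arm trait divergence
explained by validated loci ((sum 2 dp beta / D_obs)^2, capped at 1 — a
stand-in for an unstated variance decomposition), and the cold/hot
recombination-zone enrichment (10-cM windows, 1 cM/Mb cutoff, boundary
counted hot, chi-square on the 2x2 zone-by-validated table).

## The synthetic-study generator

The generator reproduces the statistical structure the analysis assumes,
not sequence-level detail. Founders are homozygous with allele
frequencies from a uniform(0.1, 0.5) spectrum; configured QTL snap to
the nearest founder-polymorphic variant (a founder-monomorphic causal
locus would carry no signal and make the study degenerate). Meiosis is
Haldane (Poisson crossovers on the cM scale, no interference) so
recombination fractions have closed forms usable as exact test oracles.
The genetic map is U-shaped per chromosome (recombination concentrated
distally, suppressed pericentromerically, as in maize), which gives the
recombination-zone analysis genuine cold and hot regions. RILs descend
by single-seed selfing (6 generations by default), BC1s by one meiosis
onto a recurrent parent, diallel F1s by direct founder sums. The trait
is purely additive (effect x dosage / 2); phenotypes add a common trial
effect and a residual scaled so the entry-mean heritability matches the
configured h2 at the configured replication. GBS-like degradation keeps
a random variant subset at a target call rate. Defaults (5 founders, 2
chromosomes x 150 cM x 200 Mb, 5,000 variants, 200 RILs/family, h2 =
0.6, 5 QTL with effects 1.2 to -0.6 rows) keep a full run in minutes.

What the generator does **not** emulate: real GBS error modes
(restriction-site dropout, strand errors), dominance and epistasis,
genotype-by-environment interaction beyond additive trial effects,
segregation distortion, and reference-bias artifacts. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every pathology of real data. One known
consequence: the accession panel draws per-variant frequencies
independently, so it carries no linkage disequilibrium and only causal
(or tightly co-selected) variants can validate in the pooled test —
validation rates there are conservative relative to LD-sharing panels.

## Numerical choices and degenerate inputs

* Dosages are 0/1/2 copies of the non-reference allele; missing is `NA`;
  MAF uses non-missing calls only; coordinates are 1-based, bins and
  windows half-open.
* Consensus merging blanks conflicting calls rather than voting;
  allele-label mismatches drop the variant with a warning.
* RIL imputation is deterministic block assignment with midpoint
  breakpoints (RIL genomes are near-homozygous founder mosaics; an HMM
  would add parameters without changing the block calls that matter);
  directly observed scaffold calls take precedence over inference;
  chromosomes without informative scaffold markers stay missing.
* Collinear variants get p = 1 and a flagged effect rather than an
  error; constant phenotypes yield p = 1 throughout.
* Variance components are floored at zero; the REML searches run on the
  log scale over [e-20, e20] and accept the zero boundary when it fits
  at least as well.
* The Gibbs sampler aborts with diagnostics on non-finite variance
  samples; sweep order is fixed genome order, so results are exactly
  reproducible under a seed (MF order-invariance holds up to Monte Carlo
  error otherwise).
* Problem sizes in the test suite (hundreds of entries, hundreds to a
  few thousand variants, permutations in the low hundreds, chains of a
  few thousand sweeps) were chosen so the whole suite exercises every
  code path at workstation scale; the acceptance script runs a mid-size
  study (about 720 entries x 3,000 variants) end to end.

## Known limitations

* Bin-level (100-kb) localization is physically limited by linkage
  disequilibrium in RIL material: within an LD block, which near-perfect
  proxy scores best is sampling noise, so ranked bins cluster around the
  strongest QTL regardless of implementation. Mb-scale localization and
  QTL-interval coverage are the meaningful recovery measures at this
  design's resolution.
* 1.5-LOD support intervals are anti-conservative at very high LOD; the
  flanking-marker expansion restores nominal-like coverage on map-marker
  scans but intervals remain approximate.
* The stepwise model inherits the known instability of forward selection
  under strong collinearity; the backward-elimination guarantee (no
  retained marker with final p >= alpha) is enforced, but the selected
  representative within an LD block is somewhat arbitrary.
* The pooled-accession test assumes approximately normal per-accession
  frequency estimates; with very small pools the quasibinomial GLM
  switch is preferable.
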