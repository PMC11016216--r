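---
title: "Methods: proteome-wide MR screening with colocalization and mediation"
author: "protMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR screening with colocalization and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protMR)
```

## The problem

Circulating proteins are a major source of drug targets, and visceral and
ectopic fat depots (visceral adipose tissue volume, liver fat and volume,
pancreas fat and volume) are key drivers of cardiometabolic risk.
Observational protein–adiposity associations are confounded; two-sample
Mendelian randomization (MR) instead uses protein quantitative trait loci
(pQTLs) as instruments: if a variant raises the protein and, through it, the
outcome, the ratio of its outcome and protein associations estimates the
causal effect. protMR implements the full screening design around this idea:
instrument selection from pQTL summary statistics, allele harmonization,
a family of MR estimators with sensitivity statistics, Bayesian
colocalization of the pQTL regions, and a two-step mediation decomposition
through intermediate risk factors — all exercised end-to-end on synthetic
GWAS summary statistics with known causal structure, because the pipeline's
correctness can only be judged against a known truth.

## Instrument selection

Candidate instruments for each protein pass, in order:

1. genome-wide significance, p ≤ 5×10⁻⁸;
2. exclusion of the MHC region, chromosome 6, 26–34 Mb (1-based,
   inclusive; GRCh37) — extended LD there makes instruments unreliable;
3. greedy LD clumping at r² < 0.001: candidates are sorted by ascending
   p-value and a variant is kept only if it is independent of every
   already-kept variant;
4. exclusion of variants associated with five or more proteins (at the
   same significance threshold, pooled across all supplied protein
   studies), a cheap guard against pervasive pleiotropy.

Instrument strength is summarized per variant as
R² = 2·maf·(1−maf)·β² (standardized trait, per-allele effect; an
alternative z²/(z² + n) form is available via `r2Method = "zscore"`) and
F = R²(n−2)/(1−R²); variants with F < 10 are removed as weak. Instruments
missing from an outcome study are replaced by the available variant in
highest LD, required to exceed r² > 0.8, ties broken by distance and then
variant id; the proxy's own outcome association is used unscaled. During
harmonization, outcome effects are re-expressed on the exposure's effect
allele (sign flip for swapped alleles, strand complementation where
needed); palindromic (A/T, C/G) variants are removed unconditionally —
their strand cannot be resolved from allele labels — and irreconcilable
allele sets are dropped as ambiguous.

## Estimators

With harmonized per-variant pairs (bx, by) and outcome standard errors
`byse`:

* **Wald ratio** (single instrument): β = by/bx, se = byse/|bx|
  (first-order; exposure uncertainty is ignored, the "no measurement
  error" convention of summary-data MR).
* **IVW**: the zero-intercept weighted regression
  β = Σ bx·by/byse² / Σ bx²/byse², identically the inverse-variance
  weighted mean of the Wald ratios with weights (bx/byse)². The default
  variance model is multiplicative random-effects (fixed-effect se scaled
  by the residual standard deviation, floored at 1): under-dispersion
  never tightens the CI, heterogeneity widens it. The fixed-effect model
  is available and is the one whose calibration is a mathematical
  property; the random-effects default is deliberately conservative.
* **MR-Egger**: weighted regression *with* intercept after orienting all
  instruments to bx ≥ 0; the intercept estimates directional pleiotropy,
  its two-sided p-value is the pleiotropy test; both coefficient ses are
  inflated by max(1, residual sd).
* **Weighted median**: the 0.5-quantile of the ratio distribution under
  inverse-variance weights, interpolated between bracketing order
  statistics; consistent while valid instruments hold > 50% of the
  weight. The se is a seeded parametric bootstrap (per-variant effects
  redrawn from their sampling distributions, default 1000 replicates).
* **Weighted mode**: argmax of a weighted normal-kernel density over the
  ratios. The default bandwidth is 0.9·s·k^(−1/5) with s the MAD of the
  ratios (falling back to the SD when a tied majority degenerates the
  MAD), scaled by `bandwidthFactor`; as the bandwidth grows the estimate
  tends to the weighted mean, as it shrinks, to the best-supported
  cluster.
* **Cochran's Q**: Σ w_j (r_j − β_IVW)² with w_j = (bx_j/byse_j)²,
  referred to χ²(k−1), the heterogeneity sensitivity check.

`mrAuto()` dispatches on the instrument count exactly as the screening
design requires: one instrument → Wald only; two → IVW plus Q (Egger,
median and mode all need at least three); three or more → everything.
All p-values are two-sided normal and CIs use ±1.96·se, reproducing the
printed-table arithmetic convention of published screens.

## Colocalization

An MR hit can be an LD artifact: the pQTL may merely be correlated with a
distinct outcome-causal variant. For each flagged pair the ±1 Mb region
around the sentinel pQTL is intersected across the two studies (MAF
strictly > 0.01 in both), and each variant receives a Wakefield
approximate Bayes factor for each trait,

log ABF = ½·[log(1−r) + r·z²],  r = W/(V + W),

with V the squared standard error and W the prior effect variance
(prior sd 0.15 × trait sd; traits are analyzed standardized, and only
quantitative-trait ABFs are implemented since all five outcomes are
quantitative). Per-variant priors p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵ (the
conventional defaults for this framework; configurable) combine the ABFs
into the five single-causal-variant hypotheses H0–H4. All sums run in log
space through log-sum-exp; the H3 sum over ordered pairs of distinct
variants uses the complement identity exp(L1+L2) − Σ exp(l1j+l2j), with
direct pairwise summation for regions of ≤ 64 variants where cancellation
could bite, and PPH3 ≡ 0 (with a recorded note) for single-variant regions
where H3 is undefined. PPH4 > 0.8 is called colocalized, 0.6 < PPH4 ≤ 0.8
suggestive. Only colocalized associations are "prioritized" by the screen.
When several pQTL regions exist per gene, the package reports per-region
posteriors and leaves gene-level aggregation (e.g. the maximum) to the
caller — an interpretation choice, flagged as such.

## Two-step mediation

For a protein flagged against an outcome, a risk factor flagged against
the same outcome (Step-1 MR), and the protein flagged against the risk
factor (Step-2 MR), the mediated path is quantified by the product method:
indirect = β1·β2 (Step-2 × Step-1), with the first-order delta-method
standard error √(β1²se2² + β2²se1²) — no covariance term, the estimates
coming from non-overlapping samples — and the proportion mediated
indirect/β3 against the total effect β3 from the primary MR, with a
delta-method CI for the ratio. Direct effect = β3 − indirect by
construction. Proportions outside [0, 1] or with sign-inconsistent paths
are reported untruncated with an inconsistent-mediation note. A reverse MR
(mediator → protein) flags bidirectionality: a reverse p-value below the
protein-family threshold marks the triple invalid, as an annotation rather
than an exclusion, since such pairs are still reported in practice.

## Multiple testing

Bonferroni control is per family: α/1002 = 4.99×10⁻⁵ for the protein
family (1002 distinct instrumentable proteins, not protein×outcome pairs
— both counts are recorded in the run manifest) and α/18 ≈ 0.0028 for the
18 risk factors. The source analysis's abstract quotes 0.0024 for the
risk-factor family while its methods and results use 0.05/18 = 0.0028;
the methods value is implemented and the discrepancy is simply noted
here rather than resolved.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is validated.

* **Scales.** Traits are standardized (SD units); variant effects are
  per-allele. A causal variant with variance explained R² gets
  b = √(R²/(2·maf·(1−maf))), oriented positive — the effect allele is
  defined as the trait-raising allele, a labeling convention with no loss
  of generality that also puts injected directional pleiotropy on the
  Egger-oriented scale. Exposure ses are 1/√(2·maf·(1−maf)·n).
* **LD.** Pairwise genotype correlation decays exponentially with
  distance, r(d) = exp(−decay·d); one parameter yields dense local LD for
  clumping, proxies and colocalization. Marginal effects propagate on the
  standardized-genotype scale, β_j = Σ_k r_jk·√(2p_kq_k/2p_jq_j)·β_k, and
  outcome ses use the same allelic convention — keeping both traits'
  regional z-landscapes peaked at the causal variant, as they must be for
  the colocalization truth labels to mean what they say.
* **Outcomes.** by_j = θ·bx_true_j + α_j + noise, with independent noise
  (two-sample design; an overlap fraction can couple the noises but
  defaults to 0) and θ the true causal effect. Direct variant→outcome
  effects (`gamma`) plant LD-confounded signals: an MR hit whose outcome
  signal sits on a *different* variant than the pQTL.
* **Defaults as study conditions.** Exposure GWAS n = 10,000 and outcome
  n = 30,000 (the imaging-cohort scale of the emulated studies);
  per-instrument variance explained drawn from [0.005, 0.05] — the real
  pQTL distribution is unpublished, so this is a modeling choice, made
  once; MAF uniform on [0.05, 0.5]; 10% of variants get palindromic
  allele pairs to exercise the harmonization filters (0 in the end-to-end
  scenario, which targets causal-structure recovery rather than allele
  bookkeeping).
* **What it does not emulate.** Individual-level genotypes, realistic
  genome-wide LD panels, imputation error, sample-size heterogeneity
  across variants, binary outcomes, population stratification. Passing
  tests demonstrate the pipeline's internal correctness under its own
  model assumptions, not robustness to everything real data can do.

`simulateScreenScenario()` builds the full study: each protein on its own
synthetic chromosome (41 variants, 10 kb spacing, decay 5×10⁻⁵), null /
causal (θ = 0.4) / confounded (θ = 0, planted outcome variant two
positions from the pQTL, LD r ≈ exp(−1) ≈ 0.37, scaled to outcome z ≈ 10)
proteins. One sentinel pQTL per protein keeps the single-causal-variant
assumption of the colocalization model true by construction; multi-
instrument behaviour is covered by `simulateMediationChain()`, which
realizes protein → mediator → outcome with disjoint 10-instrument sets
(θ1 = 0.4, θ2 = 0.3, direct 0.1, so the true proportion mediated is
0.12/0.22 ≈ 54.5%).

## Numerical and design choices

* Calibration experiments (type-I error, CI coverage) pair outcome draws
  with the *true* exposure effects — the regime in which the fixed-effect
  IVW's normal theory is exact, i.e. the "no measurement error"
  assumption holds by construction. With observed exposure effects at
  these sample sizes, the extra ratio variance θ²·n_out/(2pq·n_exp) lowers
  coverage by a few points; that degradation is a property of finite
  exposure GWAS, not of the implementation, and the null (θ = 0) behavior
  is exact either way.
* Greedy p-ascending clumping is the de-facto standard reading of
  "retain independent SNPs"; for small candidate sets it provably equals
  the brute-force independence criterion (tested).
* Ties in clumping order and proxy choice are broken deterministically
  (p-value, then id; r², then distance, then id) so fixed seeds give
  byte-identical reports.
* Bootstrap standard errors (median/mode) default to 1000 replicates and
  are seeded; the replicate count and seed are carried in the estimate's
  metadata.
* The Q p-value and every other tail probability come from R's `pchisq`
  / `pnorm`; p-values are floored at the smallest positive double so the
  (0, 1] contract survives extreme z-scores.
* Problem sizes used by the test-suite and the acceptance script — 2000
  replicates for calibration, 200 per colocalization scenario, 500 for
  mediation recovery, 20 seeds for end-to-end recovery — were chosen as
  the smallest sizes at which Monte-Carlo error is comfortably inside
  the asserted bands.

## Known limitations

Only quantitative outcomes are supported (no case-control ABFs or odds
ratios); multivariable MR, MR-PRESSO, Steiger filtering and SuSiE-style
multi-signal colocalization are out of scope; mediators are analyzed one
at a time; proxy lookup assumes the LD reference's allele orientation is
consistent between studies; bit-compatibility with any particular
published MR software is not claimed (weight normalizations and bootstrap
schemes differ across implementations in ways that matter only beyond
printed precision).
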