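---
title: "Methods: regional gray-matter deficit mapping with genetic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional gray-matter deficit mapping with genetic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control structural MRI studies of schizophrenia repeatedly find
reduced gray-matter (GM) volume, but the reductions are unevenly
distributed over the cortex. This package implements a staged analysis
that (i) localizes group-level GM loss to cytoarchitectonic parcels
(Brodmann-style areas, BAs) with a voxel-wise model and a
subsample-ranking procedure, (ii) treats "having a deficit in parcel r"
as a per-subject binary phenotype and scans SNPs for association with
it, scores subjects with a clumping-and-thresholding polygenic risk
score (PRS), and (iii) summarizes where candidate genes are expressed
in the developing cortex. Because the motivating cohort's data are not
publicly deposited, a synthetic-data module generates every input with
the statistical structure the analysis assumes, and planted ground
truth makes each stage's operating characteristics testable.

## Voxel-wise model and cluster inference

At every voxel inside the parcellation mask we fit ordinary least
squares of GM density on `[intercept, group, sex, age, TIV]` — the
Gaussian-error "GLM" of volumetric morphometry, not a link-function
model. The t statistic of the group coefficient is oriented HC − SCZ,
so positive values mean GM reduction in patients; df = n − 5. The
default contrast is one-sided (the scientific question is volume
*reduction*); a two-sided mode exists.

Cluster inference: voxels with uncorrected p < 0.001 are kept, 18-connected
components are labeled (the usual convention in volumetric cluster
software; 6 and 26 are available), and components under 100 voxels are
discarded. Family-wise error at cluster level is controlled by a
permutation max-extent null: group labels are permuted across subjects
(covariates stay with their subjects), the maximum suprathreshold
component size is recorded per permutation, and each observed cluster
gets p = (1 + #{max ≥ observed}) / (n_perm + 1). We chose permutation
over random-field theory because it is distribution-free and needs no
smoothness estimation; the null uses *unfiltered* component maxima,
which makes the correction slightly conservative for extent-filtered
observed clusters. Connected-component labeling is implemented in C++
for the permutation loop; a pure-R flood-fill oracle verifies it in the
test suite.

## Subsample ranking of parcels

To rank parcels by deficit burden robustly rather than from one
analysis, 60% of each group is drawn without replacement 100 times;
each subsample is analyzed with the voxel threshold and extent filter
(cluster-level FWE is *not* applied inside iterations — at 60% sampling
it would mostly measure permutation noise, and the single full-sample
analysis carries the FWE-corrected inference). Per iteration, each
region's burden is the proportion of its voxels surviving (proportion,
not raw count, so large parcels are not favored; a count mode exists
behind a flag). Regions are ranked per iteration (rank 1 = most
affected, ties broken by ascending label), aggregated by mean rank with
mean proportion as tie-breaker, and the top ten selected. Subsampling
is stratified by group to avoid degenerate draws.

## Per-region phenotypes and association scans

A patient "has" the region-r phenotype when their regional
density-weighted volume (Σ density × voxel volume, in cm³) is
abnormally low against the healthy-control sample. We read the
selection test as the Crawford–Howell single-case test,
t = (x − m̄_c) / (s_c √((n_c+1)/n_c)), df = n_c − 1, one-sided, which
treats the patient as one new draw from the control population; the
literal one-sample form (divisor s_c/√n_c) is provided behind a flag
because the source procedure's wording is ambiguous, but the
single-case form is the statistically defensible reading for
classifying individuals and is the default. Selection threshold:
one-sided p < 0.05.

Association: cases = selected patients, controls = all HC; per SNP an
additive logistic regression (self-implemented IRLS; zero start, 25
iteration cap, |Δ log-likelihood| < 1e-8, separation heuristics flag
non-convergence) with Wald p; missing dosages are mean-imputed per SNP
to keep n constant. No covariates by default. SNPs below 5 × 10⁻⁶ (the
fixed suggestive threshold) are flagged; no additional
multiple-testing layer is added, by design. Genotype QC precedes the
scan: SNP call rate ≥ 0.95, subject call rate ≥ 0.95, MAF ≥ 0.01,
control-group Hardy–Weinberg exact p ≥ 1e-6, applied in that order.
The HWE test is the plain exact conditional test (no mid-p), matching
common GWAS practice. Positional SNP→gene mapping uses a ±10 kb window
over IRanges; coordinates are 1-based inclusive throughout, with BED
converted on read.

A note on power: the suggestive threshold is calibrated for
study-scale cohorts (hundreds of subjects, imputed panels). At the
desk-scale default (≈35 cases vs 60 controls) the realized
case-control slope is also attenuated — cases are drawn with base rate
≈ 0.6, so the observable slope is roughly β(1 − p̄) — and no
realistic planted OR reaches 5 × 10⁻⁶. The demo therefore typically
reports zero suggestive SNPs; the detection property is validated at
the study condition (OR 3, MAF 0.3, 172 cases / 232 controls) in the
acceptance suite, where the data-generating and analysis models
coincide.

## Polygenic risk score

Discovery summary statistics are QCed (duplicate rsids dropped keeping
the first, strand-ambiguous A/T and C/G SNPs removed, SNPs absent from
the target dropped, effect alleles aligned to the target's counted
allele with beta sign flips). LD clumping is greedy by ascending p
(ties by position): a SNP is kept unless its dosage r² with a kept
index within 250 kb exceeds 0.1; the target genotypes serve as the LD
reference (no external panel at desk scale). Scores are
score(i, T) = Σ_{p_j ≤ T} β_j · dosage_ij, with missing dosages
contributing the effect-allele frequency. The threshold grid is
PRSice-like, {5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, ..., 1};
the source tool's high-resolution scan is intentionally replaced by
this coarser grid. Per threshold we fit case status on the score and
compute Nagelkerke pseudo-R²,
(1 − exp((2/n)(ℓ₀ − ℓ₁))) / (1 − exp((2/n) ℓ₀)); the best threshold
maximizes R² (ties to the smaller threshold), and scores there are
z-standardized and compared between groups with a Welch test. R² is
computed on the score alone (no covariates), matching how "phenotypic
variance explained" is usually reported in this design.

## Two-sample and correlation tests

Group comparisons default to the Welch unequal-variance t test; the
motivating study's printed whole-brain p-value (2.59 × 10⁻¹⁵ from
n = 330, 698.9417 ± 32.8024 vs n = 194, 672.5034 ± 36.79144) is
reproduced by the Welch form from summaries alone (we obtain
2.598 × 10⁻¹⁵; the pooled Student form gives 1.8 × 10⁻¹⁶), which is
why Welch is the default and the pooled form sits behind a flag.
Whether that published comparison adjusted for covariates is not
stated; the unadjusted Welch test reproduces it. Clinical correlations
(volume vs illness duration, MMSE) are Pearson r with the t-based
two-sided p, df = n − 2.

## Expression statistics

For single-cell counts, a cell is "positive" for a gene when its raw
count is ≥ 1 (the positivity criterion is undefined in the source;
raw-count ≥ 1 is the simplest auditable choice, and the threshold is a
parameter). The positive-cell ratio is tabulated per cortical area.
ISH intensities are measured in four sites (anterior/posterior plane ×
medial/lateral position); each gene-stage quadruple is normalized by
its mean, so relative values average to exactly 1. Pattern labels are
assigned deterministically from high/neutral/low flags at margin
δ = 0.1 (> 1.1 high, < 0.9 low): all-neutral → uniform; exactly two
highs → the matching paired label (axis contrasts like "anterior-high
posterior-low", or diagonal labels like "anterolateral and
posteromedial-high"); one high → "<region>-high"; three highs → the
remaining region's "-low"; with no highs, the mirrored rules on lows.
δ is qualitative in the source; 0.1 was fixed a priori and the
round-trip of every canonical pattern through its designed multipliers
is exact in the tests.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and
are not tuned per experiment:

* **Geometry** — 32³ grid, ellipsoidal brain mask (≈ 8,400 voxels),
  20 Voronoi-grown contiguous parcels (Lloyd-relaxed, each ≥ 150
  voxels), 4 mm voxels.
* **Cohort** — 60 HC + 60 SCZ (the motivating cohort's 330/194 is a
  preset, `sim_config_study_scale()`); sex balanced, age ≈ N(43, 13²)
  years, TIV ≈ N(1450, 110²) cm³, MMSE lower and more variable in
  SCZ, illness duration SCZ-only.
* **Images** — regional baselines ≈ N(0.60, 0.03²) density, nonzero
  covariate slopes (so adjustment is actually exercised), voxel noise
  sd 0.05, and a deficit of d = 0.8 × noise sd in affected regions
  (regions 1–10 by default) for flagged subjects.
* **Genotypes** — 5,000 SNPs, MAF ~ U(0.05, 0.5), Binomial(2, maf) per
  subject (HWE holds by construction), 1% missingness; 10% of SNPs in
  copy-with-flip LD pairs (flip 0.05), positions 10 kb apart on one
  chromosome so clumping windows are meaningful; A/T–C/G pairs at 5%
  to exercise PRS QC.
* **Causal structure** — one causal SNP per affected region with
  log-OR log(3); per-region case probability logistic with intercept
  set for ≈ 0.6 mean caseness among SCZ; HC are never cases. A
  200-SNP polygenic layer (|log-OR| ~ U(0.10, 0.15), random signs)
  tilts *group membership*: SCZ labels are drawn without replacement
  with weights exp(liability), a retrospective case-control
  enrichment. This link is what makes PRS group separation a testable
  recovery target; without it the target cohort would carry no
  polygenic signal at all.
* **Discovery statistics** — β̂ = true effect + N(0, 1/discovery_n),
  SE = 1/√discovery_n, two-sided Wald p; 20% of rows emitted with
  swapped alleles (sign-flipped β) and ≈ 0.2% duplicated, to exercise
  alignment QC. Default discovery_n = 2000: chosen so planted effects
  span the suggestive range of the threshold grid rather than
  saturating at p ≈ 0 (the motivating discovery study's 58,140 is the
  study-scale preset).
* **Expression** — 16 genes × 6 areas × 40 cells, negative-binomial
  counts (size 2, base mean 0.8), preferred-area multiplier 4; ISH
  intensities per pattern at multipliers 1.5 (high) / 0.6 (low) with
  5% lognormal noise, cycling through the full pattern vocabulary.

All randomness flows from one root seed through named substreams
(`substream_seed`), so stages are independently re-runnable and a
fixed configuration regenerates byte-identical outputs.

What the generator does **not** emulate: MRI physics and smoothing,
cortical topology and hemispheric structure, population stratification
and relatedness, genotyping error and imputation uncertainty,
LD beyond pairwise blocks, or any coupling between GM volumes and the
clinical covariates (the clinical-correlation stage is a null check on
synthetic data). Passing tests therefore demonstrate the correctness
and calibration of the *procedures*, not their field performance on
real cohorts.

## Numerical choices and degenerate inputs

t-distribution p-values go through R's `pt` (regularized incomplete
beta; no normal approximation). The exact HWE test is computed in log
space and normalized, so it is stable for large counts; ties in the
conditional probability are included with a 1e-12 relative tolerance.
IRLS reports honest convergence: separation heuristics (fitted
probabilities within 1e-10 of 0/1, |coefficient| > 15) force
`converged = FALSE`, and downstream consumers (the scan, the PRS grid)
treat such fits as missing rather than significant. Zero-variance
voxels get t = 0 with a flag; monomorphic SNPs are excluded from
scans; constant score vectors raise degenerate-input errors in group
comparisons; empty cluster sets, empty sharing tables and empty case
sets are all representable and tested.

## Problem sizes used in the checks

The packaged test-and-acceptance runs use: 200 random 16³ masks for
the component-labeling oracle; all genotype triples with n ≤ 30 for
the HWE oracle; 3 pooled null cohorts (24³, 25+25) for voxel-level
calibration; 40 null simulations at 200 permutations for the FWE
false-positive rate; 20 seeds × 100 iterations of 60% subsampling
(32³, 60+60, d = 0.8) for top-ten recovery; 50 replicates of the
404-subject association power condition; and 30 seeds for PRS group
separation and threshold-band recovery. These sizes were chosen as the
smallest that make the binomial acceptance bands meaningful.

## Known limitations

* Desk-scale per-region scans cannot reach the fixed suggestive
  threshold (see the power note above); gene mapping is exercised on
  constructed scans and at study scale.
* The FWE permutation null ignores the extent filter, a conservative
  simplification.
* The LD model is pairwise copy-with-flip; clumping behavior under
  realistic haplotype structure is not represented.
* The single-case selection and the subsequent association scan reuse
  the same volumes; selection-induced winner's curse in per-region
  effect sizes is inherent to the design and not corrected.
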