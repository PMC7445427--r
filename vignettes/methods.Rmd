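---
title: "Methods: the neurocascade inference pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neurocascade inference pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neurocascade` implements a multi-stage inference cascade that links two
longitudinal symptom streams (for concreteness: ADHD symptoms and sleep
disturbance in school-aged children) to brain structure and to spatial gene
expression. The stages are: (1) cross-lagged panel models that establish
the temporal direction between the two streams; (2) family-aware
permutation inference; (3) voxelwise gray-matter association with
cluster-level familywise-error correction and overlap logic; (4) bootstrap
mediation of the brain → symptom-A → symptom-B pathway, scalar and
voxelwise; (5) partial least squares (PLS) association of the mediation
map with spatially sampled gene expression. A synthetic-data module
generates every input with known ground truth, so each stage is testable
by parameter recovery without access to restricted cohorts.

## 1. Cross-lagged panel models

### Model

For streams $x$ and $y$ measured at waves $t = 1..W$ ($W \ge 3$), the
random-intercepts cross-lagged panel model (RI-CLPM) decomposes each
observed score into a wave mean, a stable between-person factor (random
intercept with loading fixed at 1), and a within-person component that
follows a lag-1 process:

$$x_{it} = \mu^x_t + \eta^x_i + w^x_{it}, \qquad
  w^x_{i,t+1} = a^x_t w^x_{it} + c^{yx}_t w^y_{it} + \varepsilon^x_{i,t+1},$$

and symmetrically for $y$. A bivariate $W$-wave model has
$2(W-1)$ autoregressive and $2(W-1)$ cross-lagged paths — 16 lagged paths
at 5 waves — which form the inference family for the
Benjamini–Hochberg FDR correction (`fdr_paths`). Paths are lag-specific by
default (the per-lag estimates are the scientific object of interest);
equality constraints across lags are available via `constrain=` because
some analysts prefer the constrained form. The traditional CLPM
(`random_intercepts = FALSE`) places the lag structure directly on the
observed variables and admits $W \ge 2$.

Time-invariant covariates enter in a second step as predictors of the two
random-intercept factors only — the between-person factors are where
stable confounders such as sex or socioeconomic status can act — while
time-variant covariates (e.g. medication status per wave) enter as
wave-specific exogenous regressors on the same-wave observed variables.
Means are free per wave; no growth structure is imposed.

### Estimation

The model is expressed in the RAM form: implied moments
$\Sigma = F(I-A)^{-1}S(I-A)^{-\top}F^\top$, $\mu = F(I-A)^{-1}m$, with
equality constraints realized as shared parameter labels. This gives a
uniform treatment of the CLPM and RI-CLPM and a trivially enumerable free
parameter count (used by the identification check $df \ge 0$).

Full-information maximum likelihood (FIML) groups cases by missingness
pattern and sums pattern-wise Gaussian log-likelihoods computed from
pattern-level sufficient statistics, so the objective cost is independent
of $n$. FIML is consistent under missing-at-random (MAR) dropout; on
complete data it equals listwise ML to numerical precision (a tested
invariant). Optimization is quasi-Newton (`nlminb`) from three
deterministically jittered starts (no RNG is consumed, so fitting never
perturbs a simulation's random stream); the best solution is kept and the
gradient norm is reported. Standard errors come from the observed
information (numerical Hessian of $-2\ell$); Heywood cases (negative
variance estimates) are warned about and reported rather than truncated.

Standardization multiplies each path by the ratio of model-implied SDs
and turns covariances into correlations, with delta-method CIs; it is
idempotent and invariant to rescaling the observed variables. Fit indices
use the FIML-saturated model (estimated by EM over missingness patterns)
and the independence baseline: RMSEA with the $(N-1)$ denominator, CFI
clamped to $[0,1]$, TLI unclamped, and SRMR from the standardized
covariance residuals against the saturated moments (covariance structure
only; mean residuals are excluded, a convention choice stated here
because software differs). With $df = 0$ RMSEA is defined as 0 and noted.

The Wald comparison of two path strengths uses
$(\hat\theta_a-\hat\theta_b)^2 / \widehat{var}(\hat\theta_a-\hat\theta_b)$
with the observed-information parameter covariance; it agrees with the
likelihood-ratio test to within 15% at large $n$ (tested). Cross-site
meta-analysis (`meta_sites`) wraps `metafor::rma`: inverse-variance fixed
effects, or DerSimonian–Laird random effects.

## 2. Family-aware permutation

Multi-site pediatric cohorts contain singletons, sibling pairs, twin
pairs and triplet sets; observations are exchangeable only within the
constraints of this structure. `build_blocks` partitions families by
composition signature (member type × size); whole families may swap only
within a signature class, and members of a multi-member family are
exchangeable with each other. The legal-permutation count is
$\prod_{classes} k! \prod_{families} (size)!$, verified against exhaustive
enumeration in the tests. `draw_permutation` samples uniformly from this
group (shuffle family order within class, then members within family).

`permute_coefficient` uses the Freedman–Lane scheme: residualize the
outcome on the nuisance covariates, permute those residuals by legal
draws, add back the nuisance fit, refit, and collect the statistic of
interest; p-values use the add-one estimator $p = (1 + \#\{|T_b| \ge
|T_{obs}|\})/(1+B)$, which is never zero. Freedman–Lane was chosen over
raw-outcome permutation because every model in the cascade carries
covariates; permuting raw outcomes would break the covariate structure
under the null. The package demonstrates in its tests that ignoring the
blocks on family-correlated data inflates the type-I error while the
block-respecting test stays near nominal.

## 3. Voxelwise gray-matter association

Images are consumed after standard VBM preprocessing (segmentation,
normalization, modulation, smoothing are out of scope). The gray-matter
mask retains voxels whose mean image strictly exceeds 10% GM. The
voxelwise GLM computes, per in-mask voxel, the OLS t of the behavioral
predictor with covariates partialled; it matches single-voxel `lm` fits
to 1e-8 (tested against 100 sampled voxels per run).

Suprathreshold clustering uses a two-sided voxel threshold (default
$\alpha = .001$, converted by the t quantile at the model dof), clusters
positive and negative voxels separately (the default because pooling signs
can merge physiologically distinct effects), and labels connected
components under 26-connectivity by default (6/18 available; the rule is
configurable because conventions differ across packages).

Cluster-level familywise error uses the permutation distribution of the
maximum cluster size: Freedman–Lane residual permutations under the
family blocks, max suprathreshold cluster size per draw, and add-one FWE
p per observed cluster. Cluster size (extent) rather than mass is the
statistic. The nominal level is per analysis ($\alpha = .05$ for a single
outcome; $\alpha = .025$ when two sleep dimensions share the error
budget). On a 20³ grid with 8-mm FWHM smoothing the max-size statistic is
strongly discrete (many null datasets have no suprathreshold voxel), so
the empirical FWER sits slightly below nominal; the acceptance test
measures it at 0.02–0.08 over 200 null studies.

Overlap between the cluster sets of two outcomes intersects voxel sets
pairwise and retains regions strictly larger than `min_voxels`
(default 217, the smoothing-kernel-derived criterion; the kernel
derivation itself is not recomputed — the threshold is a config
parameter). The operation is symmetric and is tested against set-algebra
oracles, including a constructed 419-voxel intersection.

## 4. Mediation

`mediate` fits the two covariate-adjusted regressions
($m \sim x + C$; $y \sim m + x + C$) plus the total-effect model,
yielding paths $a$, $b$, $c$, $c'$, the mediation effect $ab$, and the
identity $ab = c - c'$ which holds at machine precision in these linear
models (asserted on every fit in the tests). CIs are bias-corrected
(non-accelerated) bootstrap intervals over subject resamples — 10,000
draws by default for scalar mediation — with percentile intervals behind
a flag. When a family table is supplied, whole families are resampled
(cluster bootstrap), honoring relatedness the same way the permutation
module does. The proportion mediated $ab/c$ is reported only when
$sign(ab) = sign(c)$ and $|c|$ exceeds twice its bootstrap SE; otherwise
it is undefined with a warning, because the ratio is meaningless under
inconsistent mediation and explosive near $c = 0$.

`voxelwise_mediation` treats each in-mask voxel as the predictor,
computes $ab$ per voxel via the Frisch–Waugh–Lovell reduction (everything
residualized on covariates, then closed-form two-regressor algebra), and
forms a bootstrap-based t: $ab$ divided by its bootstrap SE (3,000 draws
by default; the t definition is stated because it is a toolbox convention
rather than a universal definition). FDR (BH) runs over all in-mask
voxels first, and final significance additionally requires a voxel–outcome
association at $p < .005$ (two-sided, uncorrected); this order — FDR over
the full mask, then the constraint intersection — follows the sentence
order of the analysis it mirrors and is stated here because the reverse
order would change the FDR family. The unthresholded t map is always
returned, because downstream spatial analyses consume it unthresholded.

## 5. Imaging transcriptomics

Probe-level preprocessing follows the standard pipeline order:
intensity-based filtering (probe kept if called above background in at
least 50% of samples), probe selection by mean (keep the highest-mean
probe per gene; mean-collapse available as an alternative mode — the
phrase "selection by mean" is ambiguous and both readings are
implemented), partition of samples into subcortical and cortical classes
analyzed independently, and within-donor normalization per gene inside
each region class (scaled robust sigmoid by default; plain z-scoring
available). Left-hemisphere-only coverage is a metadata filter
(world $x \le 0$).

The response is the mean statistic-map value in a 4-mm sphere around each
sample's coordinates (6-mm robustness runs supported), computed by
exhaustive in-mask voxel enumeration — tested to 1e-10 against an
independent brute-force oracle.

PLS1 is implemented as NIPALS with deflation; with a univariate response
the first-component weights are exactly the unit-normalized (scaled)
covariance $X_c^\top y_c$, which provides both a test oracle (cosine >
0.999, also cross-checked against mixOmics) and a fast path for the
bootstrap. Components are selected by permutation of the response (5,000
draws at production scale): per component index, the add-one proportion of
null variance-explained values at least as large as observed. Gene scores
are $z = w / SE_{boot}(w)$ with 5,000 bootstrap resamples at production
scale, each bootstrap weight vector sign-aligned to the original before
the SE is computed, and weights taken unit-norm before SE computation.
Ranked lists are exported in the two-column preranked-GSEA `.rnk` format
with top/bottom 1% gene lists (ties broken alphabetically for
determinism); enrichment itself is out of scope — the package produces
the exact input formats. Leave-one-donor-out validation reports the
Spearman correlation of each reduced run's z with the full-data z.

## The synthetic-data generators

The generators define the study conditions under which every property is
tested; their defaults emulate the cohorts' statistical structure, not
their content.

* **Families** (`gen_family_table`): member-type mix defaulting to 76.2%
  singletons, 5.6% siblings, 17.9% twins, 0.3% triplets — the composition
  of a large multi-site pediatric imaging cohort. Sibling group size is
  not specified by the cohort documentation; sibling families are
  generated as pairs. Families are assigned uniformly to sites.
* **Panels** (`gen_panel`): random intercepts + lag-1 within-person
  process + per-wave innovations, an optional family-level random effect
  (default variance 0.1) so family permutation has something to protect,
  and MAR masking whose logit depends on the previous wave's observed
  value of the same stream (slope 1). MAR-conditioned-on-observed was
  chosen because FIML's validity under MAR is exactly the property the
  estimator tests exercise; the real cohorts' dropout mechanism is
  unknown. Wave spacing is metadata: the process is lag-indexed. Masking
  draws are made for every cell whatever the rate, so runs differing only
  in `missing_rate` share all observed values (a tested invariant).
* **Voxel studies** (`gen_voxel_study`): baseline 0.5 + spherical cluster
  effects (amplitude 0.2 per unit subject score — a deliberately
  detectable planted effect) + Gaussian noise smoothed at 8-mm FWHM with
  1.5-mm voxels (standard VBM smoothing), marginal noise SD 0.1. Cluster
  scores, image noise and behavioral residuals share a family component
  with ICC 0.3, so null studies are genuinely family-correlated. The
  mediator is a linear function of cluster scores; the outcome adds a
  mediator effect (0.3) and optional direct cluster effects.
* **Expression** (`gen_expression`): 182 subcortical + 784 cortical
  left-hemisphere samples across 6 donors; driver genes' expression is
  `loading × standardized map value + N(0,1)`, others pure noise, plus
  gene-specific donor batch offsets (SD 0.4); one or more probes per gene
  (Poisson extras), with a 10% background-probe fraction that the
  intensity filter should remove.

What the generators do **not** emulate: real item content, probe
chemistry, spatial autocorrelation of gene expression beyond what the
response map induces, non-Gaussian score distributions, and scanner/site
effects on images. Passing tests therefore certify the statistical
machinery — estimator consistency, error control, recovery of planted
structure — not robustness to every artifact of real data.

## Numerical choices and degenerate inputs

* Likelihood evaluations returning non-positive-definite implied
  covariances score a large penalty rather than erroring, so the
  optimizer can retreat.
* Singular observed information falls back to a pseudo-inverse with a
  warning; negative variance diagonals yield NA SEs.
* Permutation and bootstrap p-values use add-one estimators and cannot be
  zero; non-convergent permutation refits count as exceedances
  (conservative) and are logged.
* Voxels with zero residual variance are skipped (and counted) in the
  voxelwise mediation; empty ROI spheres drop the sample with a log
  entry; an all-empty sphere set is an error.
* Ties in gene rankings break alphabetically; cluster peak ties resolve
  to the first maximal voxel.
* Proportion mediated is withheld (NA + warning) near a vanishing total
  effect, as described above.

## Problem sizes used by the test suite

The statistical acceptance checks run at sizes chosen to keep
Monte-Carlo error well inside the asserted bands: RI-CLPM recovery uses
60 replicates at n = 1,600 (bias assessed per parameter; CI coverage
pooled over all free parameters); permutation type-I uses 200
family-correlated null datasets with 500 permutations each; cluster FWER
uses 200 null image studies on a 20³ grid (n = 80, 200 permutations);
mediation CI coverage uses 150 replicates at n = 1,000 with 1,000
bootstrap draws; PLS driver recovery uses 20 seeds with 2,000 genes. The
production-scale defaults of the functions themselves (5,000
permutations, 10,000/3,000/5,000 bootstraps) are unchanged by any of
this.

## Known limitations

* No ordinal/WLSMV estimation, latent-growth, or >2 symptom streams.
* No TFCE or surface-based analysis; no sign-flipping permutation
  schemes or variance groups.
* No multi-mediator or moderated mediation.
* No spatial-autocorrelation-preserving ("spin") null maps for the
  transcriptomic stage; the permutation test permutes samples freely.
* Kinship inferred from genetics is out of scope; the questionnaire-style
  family table is the interface.
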