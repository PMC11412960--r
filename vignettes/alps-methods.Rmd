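---
title: "Models and methods behind alpskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alpskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpskit)
```

`alpskit` implements a complete DTI-ALPS glymphatic-function analysis —
simulation, tensor fitting, index extraction and group statistics — for a
chronic-tinnitus versus healthy-control study design. This vignette is the
package's own account of the models it uses, the parameters that matter,
and the choices made where the design was genuinely open.

## The diffusion model and the ALPS index

Per voxel, diffusion-weighted signal follows the monoexponential tensor
model

$$S(b, \mathbf{g}) = S_0 \exp(-b\, \mathbf{g}^\top D\, \mathbf{g}),$$

with $D$ a symmetric positive-definite $3 \times 3$ tensor (mm²/s), $b$ the
diffusion weighting (s/mm²) and $\mathbf{g}$ a unit direction. The ALPS
index reads the *diagonal* elements of $D$ in the image frame — not the
eigenvalues — inside fiber-specific ROIs at the lateral-ventricle level:

$$\mathrm{ALPS} = \frac{\tfrac12(D_{xx}^{\mathrm{proj}} + D_{xx}^{\mathrm{assoc}})}
                       {\tfrac12(D_{yy}^{\mathrm{proj}} + D_{zz}^{\mathrm{assoc}})}.$$

The x-axis is the perivascular direction there, perpendicular to both the
projection fibers (z-dominant) and association fibers (y-dominant); the
denominator takes each ROI's diffusivity perpendicular to both the fiber
and the perivascular axis. Subcortical (x-dominant) ROI diffusivities are
extracted and reported but never enter the index. The index is scale
invariant, strictly increasing in its numerator terms and strictly
decreasing in its denominator terms — properties the test suite checks
directly.

## Tensor estimation

Taking logs linearizes the signal model:
$\ln S = \ln S_0 - b\,\mathbf{g}^\top D \mathbf{g}$, a linear model in the
six unique tensor elements plus $\ln S_0$, fitted per voxel by ordinary
least squares (`fit_tensor_loglinear()`). Choices:

- **OLS by default, WLS behind a flag.** OLS is deterministic and recovers
  noiseless single-tensor signals exactly (to machine precision), which
  anchors the phantom round-trip contract; the optional weighted pass uses
  squared predicted signals as weights, the usual correction for the log
  transform's heteroscedasticity. Either way the estimator is checked
  against an independent Levenberg–Marquardt fit of the nonlinear signal
  equation.
- **$S_0$ as the seventh coefficient**, not the b = 0 mean: one consistent
  linear model.
- **Clamping:** signals are floored at $10^{-6}$ of the voxel maximum
  before the log (magnitude noise can produce near-zero samples); any voxel
  that needed clamping, contains non-finite data, or fits a
  non-positive-definite tensor is *flagged* invalid rather than dropped, so
  downstream ROI means can report their valid-voxel fraction.
- **Determinism:** eigenvalues are sorted descending and the principal
  eigenvector's sign is fixed by making its largest-magnitude component
  positive.

A gradient table must contain at least one b = 0 volume and six
well-spread directions; coplanar direction sets are rejected as
rank-deficient rather than silently pseudo-inverted.

## The synthetic cohort generator

The generator's defaults are the published study conditions: 50 subjects
per group; per-group means and SDs for nine ROI diffusivities, thirteen
neuropsychological scores and the demographic/clinical measures
(`cohort_reference_params()`); a 23/27 male/female split simulated as
Bernoulli; b = 0 plus 32 directions at b = 1000 s/mm²; and Rician noise at
SNR $S_0/\sigma = 30$, a typical magnitude-MR operating point with a
testable second-moment identity $E[S^2] = S_\mathrm{true}^2 + 2\sigma^2$.
Direction sets use a deterministic golden-angle spherical spiral — the
acquisition fixes direction *count*, not placement, and the spiral gives
near-uniform coverage without an optimization step.

**Diffusivity truths** are drawn as independent normals per diffusivity
(only marginal mean ± SD are published; no covariance is available),
truncated below at $10^{-5}$ mm²/s — more than 6 SDs below every reference
mean, so the truncation bias is far under 0.1 % of any mean. A consequence,
deliberate and documented: the per-subject ALPS index, being a ratio of
independent draws, has a population SD of about 0.217 under the tinnitus
parameters — larger than the published per-subject SD of 0.119, which
would require a positive covariance between numerator and denominator
diffusivities that the summary tables do not constrain. The published
per-subject ALPS moments are therefore carried separately
(`reference_alps_summary()`) for summary-level recomputation and power
analysis, and the simulated per-subject ALPS SD is *not* a target.

**Phantom geometry:** a 40 × 40 × 20 voxel grid at 2 mm (the acquisition's
slice thickness), six disjoint 2 × 2 × 2 ROI blocks — projection,
association, subcortical on each side — over an isotropic
$8 \times 10^{-4}$ mm²/s background. Each fiber ROI holds a diagonal
tensor with that subject's true (Dxx, Dyy, Dzz) for the fiber type, so the
orientation geometry of the ALPS method (projection ∥ z, association ∥ y,
subcortical ∥ x under the radiological frame convention) is realized
exactly. Left and right ROI values are averaged into one profile per
subject; the source analysis reports one index per subject without stating
laterality, and the bilateral average is the symmetric choice.

**Cognitive coupling.** Within the tinnitus group, TMT-B is generated as a
linear function of the subject's true ALPS plus independent noise,
$y = \mu + r\,\sigma_y z_A + \sqrt{1 - r^2}\,\sigma_y\,\varepsilon$ with
$z_A$ the standardized true ALPS, so the population correlation is the
target $r$ (−0.309 by default) while the marginal mean/SD stay at the group
values; AVLT is coupled to true Dyyproj at −0.413 the same way.
Standardizing $z_A$ needs the population moments of the ALPS ratio: these
are computed semi-analytically from $E[N/M] = E[N]\,E[1/M]$ and
$E[(N/M)^2] = E[N^2]\,E[1/M^2]$ with the reciprocal moments of the normal
denominator evaluated by numerical quadrature (`alps_population_moments()`;
the denominator mean sits > 8 SDs above zero, so the integrals are
numerically clean). Covariates — age, gender, education, hearing,
volumes — are drawn independently of the imaging truths, so marginal and
covariate-adjusted correlations coincide in expectation. Because the ALPS
ratio is mildly heavy-tailed (excess kurtosis ≈ 1), the sample Pearson
correlation at n = 10,000 has a spread of about ±0.01 around the target.

The average hearing threshold is computed per subject as the mean of left
and right rather than drawn from its own published row: the three hearing
rows cannot be jointly consistent under independent draws, so the
average's marginal SD is not targeted.

Reproducibility: per-subject seeds (truth, scores, noise) are derived
deterministically from the master seed, so any subject can be regenerated
independently and identical configurations produce byte-identical tables.

## The statistical battery

- **Group comparisons** are routed by Shapiro–Wilk (applied to each group;
  both p ≥ 0.05 → Student's pooled t, otherwise Mann–Whitney U; groups of
  fewer than 3 fall back to Mann–Whitney with a warning, constant samples
  count as non-normal). Pooled — not Welch — t is the default parametric
  branch: with the published per-group summaries (n = 50/50, df = 98) it
  reproduces the printed p-values for age, MMSE, MoCA, AVLT, TMT-A, TMT-B,
  DSST and the ALPS index at their printed rounding, identifying it as the
  convention of the original software. A Welch flag is provided. A few
  published rows (e.g. Dyyproj's 0.004, where the pooled-t recomputation
  gives 0.008) are *not* reproducible from summaries — those rows were
  evidently routed to Mann–Whitney on raw data that is not available, and
  the package treats them as out of reach rather than targets.
- **The summary-statistic form** (`pooled_t_from_summary()`) is exposed
  directly and is, by construction, exactly what the raw-sample test
  computes from its own moments — an identity the tests assert at 1e-12.
- **Mann–Whitney U** uses midranks; for $n_1 + n_2 \le 12$ the two-sided p
  comes from exhaustive enumeration of all labelings (valid under ties,
  where the null distribution of U remains symmetric), otherwise a normal
  approximation with tie-corrected variance and continuity correction. The
  approximation tracks enumeration to well under 0.01 throughout the
  rejection region; its worst-case deviation (≈ 0.015) occurs at mid-range
  p ≈ 0.4 where no decision depends on it.
- **Chi-square** (no continuity correction, df = 1) handles the sex split.
- **Partial correlation** residualizes both variables on an intercept plus
  the covariates (after rank transforms for the Spearman variant) and uses
  df = n − 2 − k with the t transform — the unique convention that
  reproduces both published adjusted (r, p) pairs at n = 50 with the five
  covariates (age, gender as 0/1, education, mean hearing, GM volume). A
  variable exactly explained by the covariates is reported as r = 0 rather
  than roundoff noise.
- **Bonferroni** multiplies by the family size, capped at 1. The family is
  configurable; the default in `compare_groups()` is the ten diffusivity
  rows (nine diffusivities + ALPS), the one table to which the original
  analysis most plausibly applied the correction — the publication invokes
  it without stating the family.
- Reported p-values are rounded half-away-from-zero to three decimals (two
  where the source tables print two), so a p below 0.0005 prints as 0.000;
  raw p-values are always retained in machine output.

## What passing tests do and do not show

The simulator emulates the *statistical* structure of the study — group
marginals, couplings, acquisition counts, magnitude-MR noise — on an
idealized block phantom. It does not emulate real anatomy: no partial
voluming, CSF contamination, fiber crossing or dispersion, motion, eddy
currents or susceptibility distortion (preprocessing is assumed done
upstream), and ROI placement is exact by construction where a radiologist
adjusts it on real color-FA maps. Passing round trips therefore validate
the estimator and index arithmetic, not robustness to acquisition
artifacts. The orientation check mirrors this honestly: with the wide
published subcortical SDs, occasional simulated subjects draw a
z-dominant subcortical tensor and legitimately fail the 20° default check,
exactly as an atypical real subject would be flagged for review.

Problem sizes in the tests and acceptance script are chosen for desk-scale
runs: full 40 × 40 × 20 phantoms where the contract is exactness (noiseless
round trip), 24 × 24 × 12 grids and 8–40 subjects for behavioral tests,
2,000 replicates for type-I calibration, 10,000 subjects for coupling
recovery, and 200 replicates for power at the published ALPS effect size.

## Known limitations

- Ratio-of-normals ALPS truths have mildly heavy tails; extreme cohorts can
  produce index outliers (the denominator floor bounds them).
- The published per-subject ALPS SD cannot be reproduced without the
  unpublished inter-diffusivity covariance (see above); group-difference
  power on fully simulated cohorts is accordingly lower than at the
  published per-subject moments.
- Mann–Whitney-routed published rows are not recomputable from summary
  statistics; they are documented, not targeted.
- ROI masks for real data are caller-supplied; the package does not search
  for ALPS ROIs on color-FA maps.
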