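---
title: "Connectivity fingerprints from weighted degree centrality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity fingerprints from weighted degree centrality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anterior temporal lobe resection cures roughly half of drug-resistant
temporal-lobe epilepsy (TLE) patients; predicting *which* half is an open
clinical problem. Resting-state fMRI offers a candidate biomarker: voxels
inside the epileptogenic network tend to show elevated *local functional
synchronization*, measurable as a hub statistic on the voxel-wise
correlation graph. This package implements a complete single-patient
("fingerprint") analysis of that idea:

1. clean each subject's 4D BOLD series (volume dropping, nuisance
   regression, band-pass),
2. compute a voxel-wise **weighted degree centrality (wDC)** map,
3. compare each patient's map against a small healthy normative sample with
   **Crawford–Howell single-case t-tests**,
4. reduce the significant-increase maps to six temporal-lobe ROI indicators
   (mesial, temporal pole, lateral neocortex; ipsi- and contralateral to the
   planned resection),
5. relate the indicators (plus significant-voxel counts) to post-surgical
   seizure freedom with a **backward-stepwise logistic regression**,
   reported with likelihood-ratio χ², Cox–Snell and Nagelkerke R²,
   Hosmer–Lemeshow calibration, a classification table and the ROC/AUC.

Group-level voxel-wise contrasts (one- and two-sample t maps with
cluster-extent inference) are provided as a companion module.

Because no patient-level data are publicly deposited, the package ships a
**synthetic cohort generator** with known ground truth, and all validation
is against that generator.

## The wDC statistic

For in-mask voxels with time series $x_i$, let $r_{ij}$ be the Pearson
correlation. The raw weighted degree of voxel $i$ is

$$\mathrm{wDC}_i \;=\; \sum_{j \neq i,\; r_{ij} > r_0} r_{ij},
\qquad r_0 = 0.25 .$$

Three reading notes, each deliberate and tested: the threshold is *strict*
($r > r_0$, not $\geq$); only positive correlations can enter; and the
self-correlation is excluded. Raw maps are z-standardized across in-mask
voxels (mean 0, sd 1, enforced to 1e-8) and *then* smoothed with an 8 mm
FWHM Gaussian — standardize-then-smooth is the order used by the degree-
centrality literature this pipeline follows, so the z map's in-mask moments
after smoothing are close to, but not exactly, (0, 1).

The engine never materializes the $V \times V$ correlation matrix: series
are unit-normalized once and correlations are produced in column blocks
(`block_size`, default 2048), so peak extra memory is $V \times$ block.
A brute-force double-loop oracle pins the implementation to 1e-10.

## Preprocessing

The cleaning chain is fixed: **drop** the first 5 volumes (scanner
equilibration), **regress** confounds, **band-pass** 0.01–0.1 Hz.

* Confounds: the Friston-24 motion expansion
  $[m(t), m(t)^2, m(t-1), m(t-1)^2]$ for 6 realignment parameters (lagged
  row zero-padded), white-matter and CSF means, and polynomial trend
  columns. The trend order is not specified by the source analysis chain;
  we default to linear (order 1, plus the constant). Global-signal
  regression is *not* performed — the nuisance list names WM and CSF only.
* Columns are rescaled to unit norm before the rank check (a projection
  no-op) so that numerically tiny regressors — squared radians of head
  rotation — are not spuriously flagged as collinear; genuinely collinear
  columns abort with their names.
* The band-pass is the *ideal* rectangular DFT filter (the convention of
  the REST/DPARSF toolbox family): bins with $f \in [0.01, 0.1]$ Hz are
  kept, everything else — including DC — is zeroed. The ideal filter is
  idempotent and passes exact in-band bins unchanged, which makes both
  properties directly testable; a Butterworth filter would satisfy neither
  exactly.
* Voxels left with zero variance are dropped from the analysis mask with a
  message, since their correlations are undefined.

## Single-case inference

With control sample mean $\bar{x}_c$, sd $s_c$ and size $N$:

$$t = \frac{x - \bar{x}_c}{s_c\sqrt{(N+1)/N}}, \qquad df = N - 1 .$$

This is the canonical frequentist "modified t-test" for one case versus a
small normative sample; the study names the test family without printing a
formula, and this form is the standard one. A voxel counts as a significant
*increase* iff the two-tailed $p < 0.005$ **and** $t > 0$; the source
tabulates only the increased direction, and whether it used $|t|$ or $t>0$
is not stated — we record $t > 0$ as our reading. Each ROI then yields a
binary indicator (any significant voxel) and the significant-voxel count as
a companion covariate. No within-ROI multiplicity correction is applied, on
purpose: the decision rule is "any voxel at $p<.005$", with `alpha`
exposed for sensitivity analyses.

Calibration of the test at $\alpha = 0.005$ with $N = 18$ controls is
verified on 20,000 null draws (within 3 binomial SE).

## Outcome model

The feature table is 6 indicators + 6 voxel counts per patient, outcome
coded **1 = seizure-free**. Backward elimination refits the model without
each remaining predictor and removes the one with the largest
likelihood-ratio p while it exceeds 0.10 — the "backward: LR" convention of
the statistical software family the source used, which names the procedure
but not the criterion. Reported per model: coefficient table (with the
outcome coding stated, since signs are meaningless without it),
$X^2 = -2(LL_0 - LL_1)$,

$$R^2_{CS} = 1 - e^{-X^2/n}, \qquad
  R^2_{N} = \frac{R^2_{CS}}{1 - e^{2 LL_0 / n}},$$

Hosmer–Lemeshow C over deciles of risk (ties kept together; with binary
predictors the effective group count collapses to the number of distinct
fitted probabilities, and below 3 groups the p-value is suppressed), the
classification table at cutoff 0.5, and the ROC with Mann–Whitney AUC
(ties credited 0.5; the trapezoidal curve integral equals the rank form to
1e-12 by construction).

With 12 predictors and 30 patients, quasi-complete separation is common;
the fitter flags it (diverging coefficients or saturated fitted
probabilities) rather than failing, and stepwise removal tests are computed
by explicit refits, which remain well-defined under separation.

The published headline numbers of the motivating cohort (76.7% correct
classification, AUC 0.777, B = −2.88/−2.91) are **not reproduction
targets**: the patient-level predictor table and the final model's
intercept were never published, so no implementation can recompute them.
What *is* checked analytically: the published pseudo-R² pair (0.39, 0.53)
follows from the published $X^2 = 15.19$, $n = 30$ and the 14/16 outcome
split, and the 2×2 margins of the published ipsilateral-mesial row imply a
log odds ratio of $\ln 11.25 \approx 2.420$, which the fitter reproduces to
1e-6.

## Group-level inference

Voxel-wise one-/two-sample pooled-variance t maps are thresholded at a
one-tailed cluster-forming $p = 0.005$ in the contrast direction,
componentized at 18-connectivity (the common face+edge convention), and
filtered at a 20-voxel minimum extent. Corrected cluster p-values come from
the permutation null of the **maximum cluster size** (group-label
permutations, or sign flips for one sample; exhaustive enumeration when
fewer distinct permutations exist than requested):

$$p_{corr} = \frac{1 + \#\{\max_{null} \geq k_{obs}\}}{n_{perm} + 1}.$$

This deliberately replaces the parametric random-field/FDR cluster
correction of the original SPM analysis — the original text is ambiguous
about the exact option used, and the permutation approach is
assumption-light, self-contained, and has the same decision structure.
Empirical family-wise error is verified at 0.05 (200 null replicates × 200
permutations, ±3 binomial SE) on smoothed-noise maps, which is the
regime this pipeline actually feeds into group inference (smoothed z maps;
smoothness also gives the discrete max-size statistic a rich enough null
for a two-sided check).

## The synthetic world

Each voxel time series is

$$x_v(t) = \lambda_v\, s_{R(v)}(t) + g(t) + \varepsilon_v(t),$$

with a unit-variance latent $s_R$ *shared within each atlas region*
(independent across regions), a global signal $g$, and white noise
$\varepsilon$. A planted hub ROI has $\lambda_v = \lambda$; everything else
in the brain uses $\lambda_0$. Two same-hub voxels then have
$\rho = \lambda^2 / (\lambda^2 + \sigma^2)$, so the default
$\lambda = \sigma = 1$ plants within-hub $\rho = 0.5$. Latents are
pre-filtered to 0.01–0.1 Hz and rescaled (default on) so the planted
structure passes the preprocessing band-pass unattenuated, while the white
noise loses ~64% of its variance there — post-filter within-hub correlation
is therefore ~0.7.

Simulation defaults *are* the cohort being emulated: 110 volumes at TR 2 s,
3×3×4 mm voxels, 18 controls, 30 patients. Hub planting probabilities
default to the observed ipsilateral marginal rates (mesial 7/30, pole
17/30), and outcomes are drawn from a logistic model on the true hub
indicators with the published coefficient magnitudes (+2.88 mesial, +2.91
pole on the seizure-free coding). The intercept −2.5 is the value that
makes the expected seizure-free fraction match the observed 14/30 under
those rates: averaging $\mathrm{logit}^{-1}(-2.5 + 2.88 I_m + 2.91 I_p)$
over the four indicator combinations gives 0.47. Patient effect sizes were
never characterized in the source, so $\lambda$ defaults are calibration
choices of this package, not estimates.

Two parameters were calibrated during development, once, and deserve
honesty about why. With 105 frames band-passed to 0.01–0.1 Hz, a
correlation estimate keeps only ~38 effective degrees of freedom, so
$\hat{r}$ has sampling sd ≈ 0.16; *any* appreciable sub-threshold true
correlation puts thousands of voxel pairs on the knee of the $r > 0.25$
threshold and makes baseline degree maps noise-dominated. The baseline
loading is therefore $\lambda_0 = 0.15$ (true within-region $r \approx
0.06$ post-filter) and the global signal sd 0.05 — "weak" in the sense
that actually matters, relative to the threshold and the sampling noise.
For the same reason the toy atlas keeps all twelve blocks (six temporal
ROIs, six rest-of-brain fillers, mirror-symmetric, background zero) at the
same ~100–125-voxel scale and separates ROI blocks by ≥ 2–3 voxels, so
8 mm smoothing cannot bleed one ROI's hub into another.

What the generator does **not** emulate: hemodynamic convolution, motion
spikes and their interaction with slice timing, physiological noise
spectra, spatial autocorrelation of the noise floor, registration error,
or any anatomy. A green hub-recovery test therefore establishes that the
*pipeline arithmetic* recovers planted local-synchronization structure at
realistic scan lengths and sample sizes — not that the biomarker works in
real brains.

## Reproducibility and numerical choices

* One master seed spawns per-subject substreams, so any subject can be
  regenerated in isolation; the pipeline writes a manifest with parameters
  and md5 hashes, and identical configurations reproduce identical hashes.
* Logistic fits: IRLS with log-likelihood tolerance 1e-8, max 100
  iterations (via `stats::glm`).
* Smoothing uses symmetric-reflection boundaries, so constant maps are
  preserved exactly; per-axis sigmas honour anisotropic voxels through the
  affine.
* Ties in ROC cutoffs and in Hosmer–Lemeshow risk groups are kept
  together deterministically.
* NIfTI-1 I/O is a minimal in-package reader/writer (sform affine,
  gzip-aware, float/int types) because the execution environment provides
  no R NIfTI package; it is cross-checked against nibabel in the test
  suite.

## Known limitations

* The stepwise procedure inherits all the usual criticisms (optimistic
  in-sample fit, unstable selection at n = 30); it is implemented because
  it is the analysis being reproduced, not because it is recommended.
  No cross-validation is provided, matching the in-sample scope.
* Crawford tests share one normative sample across voxels and patients, so
  ROI indicators are correlated across patients; the cohort table is
  descriptive, not inferential.
* The permutation cluster correction substitutes for the original
  parametric correction; cluster-level p-values are not comparable
  point-for-point with the published ones.
* With very small cohorts the outcome model may be skipped (single-class
  outcome) or truncated to an identifiable predictor subset; both paths
  are logged.
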