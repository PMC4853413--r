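---
title: "Functional connectivity density mapping: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdmap)
```

## The measure

Functional connectivity density (FCD) is a voxel-wise degree-centrality
measure for resting-state fMRI. After temporal cleaning, voxel $i$ is
declared functionally connected to voxel $j$ when the Pearson correlation
of their BOLD time series exceeds a threshold, conventionally $r > 0.6$
(strictly greater; negative correlations never connect). Writing
$S_{ij} \in \{0, 1\}$ for that binarized connection over the $N$
gray-matter voxels, the package computes three raw degree maps per subject:

- global FCD: $\mathrm{gFCD}_i = \sum_{j=1}^{N} S_{ij}$ (self-pairs
  excluded, so values range $0 \dots N-1$),
- contralateral FCD: $\mathrm{cFCD}_i = \sum_{j=1}^{N} h_{ij} S_{ij}$,
  where $h_{ij} = 1$ exactly when $i$ and $j$ lie in opposite hemispheres,
- ipsilateral FCD: $\mathrm{iFCD}_i = \mathrm{gFCD}_i - \mathrm{cFCD}_i$.

Hemisphere membership comes from the sign of the world $x$ coordinate
under the RAS convention ($x < 0$ left). Voxels exactly on the midline
plane are labelled `M` and participate in global degree but never in
contralateral counts; the decomposition $g = c + i$ still holds exactly
because ipsilateral is defined by subtraction.

Each subject's three maps are then divided by that subject's mean raw
gFCD over the mask, so the mask average of normalized gFCD is exactly 1.
This removes individual differences in overall connectivity level, which
would otherwise dominate group contrasts; a consequence worth keeping in
mind is that purely global (brain-wide) coupling differences are
invisible in normalized maps — only regional deviations from a subject's
own average survive. The group analysis therefore asks where connectivity
is *fractionally* reduced, not whether the whole brain is.

## Temporal preprocessing

`preprocess_subject()` applies, per masked voxel and in this order:

1. **Linear detrending** — OLS residual on an intercept plus ramp,
   removing slow scanner drift together with the mean.
2. **Nuisance regression** — OLS residual on an intercept plus the
   supplied regressors (head motion, white-matter, CSF and global
   signals). Rank-deficient designs are rejected with the collinear
   columns named.
3. **Band-pass filtering** at 0.01–0.08 Hz, the conventional
   resting-state band.

The filter is an ideal (rectangular) filter in the discrete Fourier
domain with inclusive band edges; DC is excluded. An ideal filter was
chosen over an IIR/FIR realization because it is idempotent, exactly
linear, energy-contractive, and reproducible bit-for-bit against a direct
DFT-zeroing oracle — properties the test suite exploits. Its sharp edges
ring on broadband transients, which is immaterial here because the next
step (correlation) is computed on the whole filtered record. One
practical note: probing the filter with a sinusoid whose frequency is not
an integer number of cycles per record leaks a percent-level amplitude
across bins (spectral leakage of the finite window, not a property of the
filter); the unit contracts therefore use bin-aligned probes.

Optional spatial Gaussian smoothing (default FWHM 8 mm when enabled,
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, converted to voxels
through the affine scales) runs before the temporal stages, mirroring
pipelines that smooth during spatial preprocessing. Boundaries use
reflective padding and the kernel is normalized, so constants are fixed
points and total intensity is conserved. The stage order is enforced —
regression and filtering do not commute — and each temporal stage is a
projection or spectral truncation, so per-voxel energy can only decrease.

Motion scrubbing/censoring is deliberately absent, as is any spatial
normalization: inputs are assumed to already sit on a common grid.

## The degree computation

Correlations are evaluated blockwise: the masked series are centred and
scaled to unit norm once, then an $N \times b$ panel of correlations is
formed per BLAS multiplication and immediately reduced to counts, so the
full $N \times N$ matrix is never materialized. Because every correlation
is the same standardized dot product regardless of panel boundaries, the
counts are invariant to the block size and bit-identical to an exhaustive
double loop — an equivalence the tests assert directly against a
brute-force oracle.

Zero-variance voxels (common at mask edges after masking) are dropped
from the working mask with a warning rather than failing the subject;
dropped voxels carry 0 in all output maps. An entirely disconnected
subject (mean gFCD of 0) is an error, since normalization is undefined —
real gray matter is never disconnected at $r > 0.6$, so this signals a
data or masking problem.

## Group statistics

`voxelwise_glm()` fits $y_v = \beta_0 + \beta_g\,\mathrm{group} +
\beta_a\,\mathrm{age} + \beta_s\,\mathrm{sex} + \varepsilon$ at every
masked voxel by OLS, with group coded control = 0 / case = 1 so negative
$t = \hat\beta_g / \mathrm{se}(\hat\beta_g)$ means lower FCD in cases;
two-tailed p-values use $n - 4$ degrees of freedom. With the covariates
removed the statistic reduces exactly to the classical pooled-variance
two-sample t — a reduction the tests check to $10^{-10}$. Voxels with
zero residual variance (e.g. a map identically zero in both groups) are
reported as $t = 0$, $p = 1$ rather than NaN, which is the correct
"no evidence" behavior for FDR input.

Voxel-level multiple testing uses the Benjamini–Hochberg step-up
procedure (`p.adjust`'s BH method behind the package's `bh_correct()`
surface), with significance at corrected $p < 0.05$; BH was also the
named procedure at the correlation stage, and using it voxel-wise keeps
the two stages consistent. Surviving voxels are grouped into connected
components under 18-neighbor connectivity (faces + edges, the convention
of SPM-style cluster reporting; 6 and 26 are available), and components
below 20 voxels — the conventional extent minimum — are discarded. Each
cluster reports its size, peak $|t|$ voxel in world mm, and mean t.

Clinical association uses partial correlation: both the regional FCD
summary (mean or max over a cluster's voxels) and the severity score are
residualized on an intercept, age and sex, and the Pearson correlation of
the residuals is tested with $df = n_\mathrm{complete} - 4$. Pearson (not
Spearman) residual correlation was chosen; the df accounting matches the
two-covariate convention. Missing scores are dropped pairwise per test,
and BH correction is applied across the regions/measures tested.

## The phantom generator

Synthetic subjects give every stage a planted, analytically tractable
ground truth. Voxel $v$ in network $k$ has

$$x_v(t) = \sigma\left(\sqrt{w_k}\, z_k(t) + \sqrt{1 - w_k}\,
\varepsilon_v(t)\right),$$

with $z_k$ and $\varepsilon_v$ independent unit-variance Gaussian white
noise, so the expected correlation of two same-network voxels is exactly
$w_k$ and the expected degree of a member voxel is (members − 1) when
$w_k$ clears the threshold and 0 otherwise. Voxels in no network are pure
noise. White (rather than autocorrelated) processes keep the null exact:
off-network sample correlations at 200 timepoints essentially never reach
0.6, so expected off-network degree is 0. Homotopic networks place a
voxel set and its mirror image across the midline on one shared latent
signal, emulating bilateral resting-state networks; unilateral networks
stay within one hemisphere. Network couplings are clamped to
$[0, 0.97]$.

Defaults follow the cohort's flavor without attempting to replicate it:
ages Uniform(8, 30) years, sex Bernoulli(0.85 male), TR 2 s, 200
timepoints. Four nuisance regressors are always simulated and written,
but their contamination amplitude defaults to 0 so the closed-form
correlation targets hold exactly; raising the amplitude exercises the
nuisance-regression stage.

Group effects multiply a network's coupling for case subjects
(`group_effect = 0.5` with $w = 0.8$ puts cases at $w = 0.4$, below
threshold — planted under-connectivity). For clinical scores, each
subject draws a coupling multiplier $u_s \sim \mathrm{Uniform}(0.8, 1.2)$
applied to the *designated score network only*, and
$\mathrm{score}_s = \alpha + \beta\, z(u_s) + \mathcal{N}(0,
\sigma_\mathrm{score})$ with $z(\cdot)$ standardized within the cohort,
so $|\beta|/\sigma_\mathrm{score}$ directly sets the planted effect size.
The restriction to one network is deliberate and instructive: a
multiplier applied to the whole brain is cancelled exactly by per-subject
normalization (we verified the planted correlation collapses to zero),
so a detectable clinical association must be regional relative to a
stable background — which is also the structure such associations have
in real data. Recovery experiments therefore include background networks
so every subject has nonzero global connectivity and normalization is
always defined.

What the phantoms do **not** emulate: hemodynamic response shapes,
physiological noise spectra, temporal autocorrelation (deliberately
omitted — white processes keep the correlation nulls and the analytic
degree targets exact), scanner artifacts, multi-site
heterogeneity, or spatial autocorrelation of noise. Passing the planted
recovery tests shows the statistical machinery is correct under the
stated model; it does not certify performance on real multi-site data.

## Numerical choices and problem sizes

- Correlation threshold 0.6 (strict), FDR level 0.05, cluster extent 20
  voxels, 18-connectivity, band 0.01–0.08 Hz: the conventional defaults,
  recorded in every run manifest.
- The validation experiments use grids a scientist can iterate on at a
  desk: degree calibration on a 12×10×10 grid with 15+15-voxel homotopic
  and 30-voxel unilateral networks at $w = 0.8$, T = 200, averaged over
  20 seeds (analytic targets: cFCD 15, iFCD 14 / gFCD 29, cFCD 0);
  group recovery on a 16³ grid with a 27+27-voxel planted network
  (3×3×3 per hemisphere, so each component can clear the 20-voxel extent
  minimum), cohorts of 30 + 30 over 10 seeds planted and 10 null;
  clinical recovery on a 10×10×8 grid with $n = 60$ over 10 seeds.
- Determinism: every simulation takes an explicit seed; cohort-level
  draws happen before subject volumes so tables are reproducible whether
  or not volumes are materialized; rerunning the pipeline with one
  config + seed reproduces byte-identical artifacts (checksummed in the
  manifest).
- Degenerate inputs have defined behavior: constant series are rejected
  (`correlation_degree`) or dropped with a warning (`fcd_maps`);
  constant covariates are dropped with a warning; fully disconnected
  subjects, rank-deficient designs and undefined correlations raise
  informative errors.

## A worked example

```{r example, eval = FALSE}
# a homotopic network reduced in cases, plus unilateral background
# networks so every subject keeps nonzero global connectivity
nets <- list(
  network_spec(as.matrix(expand.grid(2:4, 7:9, 7:9)), coupling = 0.8,
               laterality = "homotopic", group_effect = 0.5),
  network_spec(as.matrix(expand.grid(2:4, 2:4, 2:4)), coupling = 0.8,
               laterality = "unilateral-left"),
  network_spec(as.matrix(expand.grid(9:11, 2:4, 2:4)), coupling = 0.8,
               laterality = "unilateral-right"))
spec <- phantom_spec(c(12, 10, 10), networks = nets)
grid <- make_phantom_grid(spec)

sub <- simulate_subject(grid, spec, group = "control", seed = 1)
clean <- preprocess_subject(sub$volume, sub$nuisance, grid$mask)
maps <- fcd_maps(clean, grid)
mean(maps$c_raw[network_members(grid, spec)])  # ~27: the mirrored partners

co <- simulate_cohort(grid, spec, n_case = 30, n_control = 30, seed = 1,
                      keep_volumes = FALSE)
Y <- cohort_fcd_matrix(co, measures = "c_norm")
an <- fcd_group_analysis(Y$c_norm, co$cohort, grid)
an$clusters
```

## Known limitations

- Pearson correlation only; the weighted (non-binarized) and
  radius-split (local/long-range) FCD variants are out of scope.
- No site harmonization or mixed-effects modelling; the GLM adjusts for
  age and sex only.
- Cluster inference is FDR + extent, not permutation- or RFT-based.
- The ideal band-pass assumes regularly sampled series with no missing
  volumes (no scrubbing support).
- Whether the normalization average should run over gray matter only or
  all in-brain voxels is a convention; this package uses the gray-matter
  mask.
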