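---
title: "An upper limit on the free-water fraction from single-shell DTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An upper limit on the free-water fraction from single-shell DTI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freewater)
```

## The problem

Cerebrospinal fluid and edema contribute a compartment of *free water* to
many brain voxels: water that diffuses isotropically and unimpeded, at the
diffusivity of bulk water. Partial-volume contamination by free water
biases every standard DTI index, yet estimating the free-water volume
fraction `f` properly requires either multi-shell acquisitions or
regularized model fitting, because in the two-compartment model

$$D_{vox} = (1-f)\,D_t + f\,D_W I$$

`f` has no unique solution from a single-shell measurement (one equation
short: the tissue tensor $D_t$ is unknown).

This package computes a quantity that *is* identified from a single-shell
scan: an **upper limit** on `f`. In the eigenframe of the voxel tensor,
each eigenvalue satisfies $\lambda_i = (1-f)\Lambda_{ii} + f D_W$ with
$\Lambda_{ii} \ge 0$ for a physically valid (positive semidefinite) tissue
tensor, so $\lambda_i / D_W \ge f$ for every axis. The smallest eigenvalue
gives the tightest bound:

$$f_{UL} = \min\left(1, \frac{\lambda_3}{D_W}\right).$$

The clamp at 1 (and, in this implementation, at 0) absorbs noisy fits
whose eigenvalue ratio leaves the physical range; the clamp events are
recorded in a QC mask rather than hidden.

## The water-diffusivity constant

$D_W$ is the self-diffusion coefficient of bulk water at brain
temperature. `water_diffusivity()` interpolates linearly between the
tabulated reference values 2.30e-9 m²/s at 298.15 K and 3.55e-9 m²/s at
318.15 K:

```{r}
water_diffusivity(310)      # m^2/s, ~3.04e-9 at the default 310 K
```

Temperatures are accepted over [273, 330] K with a warning outside the
physiological band [306, 314] K. A ±2 °C brain-temperature excursion moves
the constant over roughly 2.92–3.17e-9 m²/s, and a realistic ±0.5 °C over
3.01–3.07e-9 m²/s; since a warmer assumed brain (larger $D_W$) shrinks the
ratio, uncertainty in temperature translates monotonically into $f_{UL}$.
Map production uses the 3-significant-figure constant in DTI-native units,
`default_water_diffusivity()` = 3.04e-3 mm²/s. All mapping code works in
mm²/s; only `water_diffusivity()` speaks m²/s, matching how the reference
values are tabulated. Keeping one canonical internal unit avoids silent
factor-of-1e6 errors; `compute_ful()` itself is unit-agnostic as long as
both arguments share a unit.

## Tensor estimation

The tensor is fitted voxelwise by log-linear least squares on
$\ln(S_i/S_0) = -b_i\, g_i^T D\, g_i$, with $S_0$ the mean of all volumes
with $b \le 50$ s/mm² (the b0 threshold is configurable). Ordinary least
squares is the default because it is the canonical deterministic
single-tensor estimator; weighted least squares with weights $S_i^2$ (the
first-order variance correction for log-transformed Rician data) is
available via `method = "wls"`. The fit requires at least one b0 volume
and six diffusion-weighted directions spanning all six tensor components;
anything less is a hard error, checked through the rank of the design
matrix rather than a direction count alone.

Numerical edge cases are handled as follows:

* Non-positive diffusion-weighted signals (possible after noise) cannot be
  log-transformed. They are floored to `1e-6 * S0` and the voxel is
  flagged (QC bit 1) instead of aborted.
* Negative fitted eigenvalues are retained through eigendecomposition —
  they carry information about noise — and only handled at the f_UL stage,
  where a negative ratio is clamped to 0 and flagged (QC bit 2). A volume
  fraction cannot be negative; reporting the clamp rather than the raw
  negative value was a deliberate choice, mirrored by the clamp at 1
  (QC bit 4) for ratios above unity.
* Under degenerate (equal) eigenvalues the eigenvector basis is not
  unique; the package never relies on individual eigenvectors in that
  case, only on eigenvalues and on reconstruction of the tensor, and the
  tests do the same.

Fractional anisotropy uses the standard normalized eigenvalue-dispersion
form $\sqrt{3/2}\,\|\lambda-\bar\lambda\|/\|\lambda\|$, defined as 0 for
an all-zero tensor; mean, axial and radial diffusivity are
$\bar\lambda$, $\lambda_1$ and $(\lambda_2+\lambda_3)/2$.

## What the phantom emulates — and what it does not

`build_phantom()` generates single-shell DWI volumes with known ground
truth so that every stage is testable without external data. The default
spec uses a 32×32×32 grid, 2 mm isotropic voxels, one b0 plus 15
directions at b = 1000 s/mm² (a typical clinical single-shell protocol;
directions from a deterministic spherical Fibonacci lattice), baseline
signal 1000, and five z-slabs:

| material | f | tissue tensor (mm²/s) |
|---|---|---|
| CSF | 1 | (irrelevant at f = 1) |
| gray-like | 0.10 | isotropic, MD 0.9e-3 |
| white-like | 0.02 | prolate, diag(1.7, 0.5, 0.5)e-3 |
| planar | 0.05 | oblate, diag(1.2, 1.2, 0.3)e-3 |
| gradient slab | 0 → 1 along x | prolate, diag(1.7, 0.5, 0.5)e-3 |

Tissue diffusivities sit in the empirically observed brain range
(gray-like MD ≈ 0.9e-3, white-like radial ≈ 0.5e-3 mm²/s). The
partial-volume fractions of the tissue materials are not dictated by any
measurement; they were fixed once at small realistic values, and the
gradient slab covers the full fraction range regardless.

Two mixing modes are provided. `"tensor"` mixes at the tensor level and
then applies a single exponential — exactly the linearity assumption the
bound is derived under, so noiseless tensor-mixing phantoms must satisfy
the closed form

$$f_{UL} = f + (1-f)\,\frac{\lambda_3(D_t)}{D_W},$$

which the tests assert voxelwise (and which shows $f_{UL} \ge f$, with
equality iff $\lambda_3(D_t) = 0$ or $f = 1$). `"signal"` mixes
bi-exponentially per compartment — the physically realistic behaviour the
linear model approximates. For signal-mixing phantoms no exact closed form
holds under a single-tensor fit; the tests assert only that $f_{UL}$ stays
in [0, 1] and that pure-CSF voxels still read 1.

Noise is Rician (magnitude-MRI standard): each signal is replaced by
$\sqrt{(S+n_1)^2+n_2^2}$ with Gaussian $n_1, n_2$. The generator's Rician
bias is verified against the analytic Rice mean in the tests. One integer
seed in the spec drives all draws, and the builder restores the session
RNG state, so output is bit-reproducible.

What the phantom does **not** emulate: eddy-current and susceptibility
distortion, motion, crossing fibers, spatially varying noise, multi-shell
schemes, and scanner-specific gradient tables. Passing phantom tests
therefore demonstrates the correctness of the mathematics and the
pipeline plumbing, not robustness to real-scanner artifacts; on real data
the QC mask and clamp statistics are the honest summary of where the
model struggled.

## Region statistics

`region_report()` mirrors the shape of an atlas-based analysis: per-label
voxel counts, mean ± sd of each index, and Pearson correlations of each
index against f_UL with two-sided p-values from the exact t-transform
(uncorrected; significance starred at P < 0.05). Maps and labels must
share a grid — registration and resampling are deliberately out of scope,
so statistics stay decoupled from any particular normalization toolchain.
Voxels carrying fit-failure or floored-signal flags are excluded from the
summaries (the reported `pct_included` makes the exclusion visible);
clamp flags do not exclude a voxel, because clamping is part of the
measure's definition. A zero-variance column is reported as `NA`, never
as a zero correlation.

A useful structural fact, asserted in the tests: with a fixed tissue
tensor and varying f, both radial diffusivity and f_UL are affine in f,
so their Pearson correlation is exactly 1 in the noiseless gradient slab
— the collinearity that makes f_UL track radial diffusivity so closely in
practice. For plotting, `subsample_stride()` thins voxel values
deterministically (every k-th value) and `fraction_histogram()` uses
fixed [0, 1] bin edges so histograms are comparable across runs.

## Problem sizes and determinism in the test suite

The shipped tests use a 10×10×15 phantom for unit/integration checks and
one 32³ phantom for the end-to-end CLI check; the property suites use
2,000 (unit) and 10,000 (acceptance) randomized two-compartment specs and
1,000 random tensors for the fit/eigen round trip — sizes chosen so the
whole suite completes in about a minute while leaving the randomized
checks dense enough to be meaningful. All randomized tests run under fixed
seeds; eigendecomposition is cross-checked against an independent
characteristic-polynomial root solver, and the Rician noise model against
the closed-form Rice mean.

## Known limitations

* f_UL is an upper bound, not an estimate: in dense tissue with little
  free water it can sit far above the true f (the bound gap is
  $(1-f)\lambda_3(D_t)/D_W$). It is most informative where f is large.
* The bound's validity argument assumes a PSD tissue tensor and
  $\lambda_i \le D_W$; noisy real data violate these per-voxel, which is
  why map production reports clamp flags instead of enforcing validity.
* Single-shell, Gaussian-diffusion, single-tensor modelling throughout;
  no registration, no multi-shell free-water elimination.
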