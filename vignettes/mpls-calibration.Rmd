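---
title: "Calibrating mineral content from NIR spectra with MPLS"
author: "mplsnir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating mineral content from NIR spectra with MPLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplsnir)
```

## The problem

Near-infrared reflectance spectroscopy records absorbance, log(1/R), of a
crushed sample over 1100–2000 nm (2 nm steps, 451 channels here).  Mineral
elements have no NIR absorption of their own; they are predictable only
through their association with organic chromophores — in propolis, chiefly
the flavonoids that chelate metals, and the water O–H overtones near 1400
and 1900 nm.  Given a set of samples with reference concentrations from
ICP-OES/ICP-MS, the task is to build, per element, a regression from
spectrum to concentration (mg/kg) that survives honest cross-validation
and external validation.

`mplsnir` implements the complete workflow: scatter correction and
derivative pretreatment, spectral and chemical outlier elimination, modified
partial least squares (MPLS) regression with grouped cross-validation, the
standard calibration/validation statistics, and a synthetic propolis-like
data generator used to exercise and test the whole chain.

## Pretreatments

Diffuse-reflectance spectra of powders carry multiplicative and additive
scatter unrelated to composition.  Four corrections are provided, all
standard:

* **SNV** — each spectrum centered and scaled to unit SD (n−1 denominator).
  Stateless.
* **MSC** — each spectrum regressed on the *training-set mean* spectrum,
  `x ≈ a + b·m`, corrected as `(x − a)/b`.  The reference `m` is the only
  stateful pretreatment quantity; it is stored and reused unchanged at
  prediction time.
* **Detrend** — subtraction of the least-squares quadratic in wavelength
  (degree exposed as a parameter); SNV-DT applies SNV then detrend.
* **Gap-segment derivative** — the four-number "math treatment" code
  `D,G,S1,S2`: boxcar smoothing over `S1` channels, the gap difference
  `Δx(i) = x(i+⌈G/2⌉) − x(i−⌊G/2⌋)` applied `D` times, then smoothing over
  `S2` channels.  Edge channels without full support are trimmed, never
  padded, and each step re-centers the retained grid on its window
  midpoints, so the output grid stays uniform.  `0,0,1,1` is the identity.

Treatment strings are parsed exactly as printed in calibration tables
(`"Standard MSC 1,4,4,1"`, `"SNV only 2,4,4,1"`, …).  The composition
order is scatter correction first, then derivative; the order is a
documented default rather than a universal convention, and is applied
identically at training and prediction time through the stored state.

## Outlier screening

Two criteria, applied in this order:

* **Global H** (spectral).  A PCA is fit on the pretreated calibration
  spectra and each sample's Mahalanobis distance from the population mean is
  computed in standardized score space, divided by the number of components:
  `H_i = (1/k) Σ_f (t_if/s_f)²`.  The training-set mean of H is then exactly
  `(n−1)/n ≈ 1`, which makes the conventional cutoff H > 3 meaningful.
  Elimination is a single simultaneous pass.  The score space is capped at
  the calibration's factor budget (16 components by default): derivative
  treatments whiten spectra so sharply that reaching 99% variance can take
  40+ components, at which point the metric would be dominated by noise
  directions and the model unidentifiable at n ≈ 70.
* **T criterion** (chemical).  After a calibration is fit, residuals are
  standardized by their sample SD and samples with |t| > 2.5 are removed,
  the model refit and re-cross-validated; at most two passes (the threshold
  is standard, the iteration cap is this package's choice — it prevents the
  shrinking-SD spiral in which repeated refits chase an ever-tighter
  residual distribution).

## MPLS regression

Single-response PLS1 by NIPALS deflation with one modification: after each
factor is extracted, the spectral residuals at every wavelength are divided
by their standard deviation before the next factor is computed.  Per factor,
on the current working matrix: `w ∝ X'y` (unit norm), `t = Xw`,
`p = X't/t't`, `q = y't/t't`, deflate `X ← X − tp'`, `y ← y − tq`, then
record the per-column residual SDs `s_f` and rescale the columns.  Only the
X residuals are standardized; the y residuals are not.  Zero-SD residual
columns get scale 1 with a warning.

Prediction replays the identical transform sequence, which also collapses
into the linear form `ŷ = β0 + Σ β_λ x_λ`; the package verifies recursion
and collapsed form against each other, and verifies that with all scalings
forced to 1 the fit coincides with an independent closed-form PLS1 (a
Krylov-subspace least-squares construction in the test suite) to 1e−8.
These two equivalences pin down the deflation bookkeeping, which is the one
genuinely under-specified part of the algorithm; the exact internal scaling
used by commercial software is proprietary, so the implementation is fixed
by self-consistency rather than bit-compatibility.

**Cross-validation.**  The calibration set is split at random (seeded) into
six groups; each group is predicted by a model trained on the other five,
with the pretreatment state and the MPLS fit recomputed inside each fold so
nothing leaks from the held-out group.  RMSECV is pooled over all samples at
each factor count; the selected count is the global minimum of RMSECV
(capped at 16 factors), with a one-standard-error rule available behind
`selection = "onese"`.  Ties break toward fewer factors.

**Treatment grid search.**  The default grid is the cross product of
{None, SNV, MSC, Detrend, SNV-DT} × {0,0,1,1; 1,4,4,1; 2,4,4,1; 2,10,10,1}
— twenty treatments, compared on the same seeded folds; the winner is the
lowest RMSECV at its selected factor count.

## Reported statistics

Per element, the calibration summary mirrors the conventional table: N
(survivors), mean, SD, the applicability bounds Est.Min = max(0, mean − 3SD)
and Est.Max = mean + 3SD, RMSEC, R² (squared Pearson correlation of fitted
vs reference — not 1 − SSE/SST), RMSECV, and RPD = SD/RMSECV.  External
validation on held-out samples reports RMSEP = √(Σe²/n), bias = mean(e),
the bias-corrected RMSEP(C) = √(Σ(e−bias)²/(n−1)), and RPD = SD/RMSEP(C);
the identity RMSEP² = bias² + RMSEP(C)²·(n−1)/n is audited on every report
row before anything is written.  RMSE uses the plain-n denominator
throughout (the convention that makes the printed external RPD and bias
identities mutually consistent); RMSEP(C) uses n−1 per the SEP convention.
RPD above 2 is conventionally a good calibration, below 1.5 poor.

## The synthetic generator

`synthetic_config()` describes a propolis-like study: 91 samples from three
regions (52/16/23), eleven elements, triplicate spectra, and a 71/20
calibration/validation split.  It exists so the pipeline can be exercised
end-to-end against known ground truth; its defaults are the study conditions
the package is tested under.

* **Concentrations.**  Per region and element, a truncated log-normal
  matched to the regional mean and observed range (concentrations are
  positive and right-skewed).  The range is treated as the expected range of
  n draws — width 2·Φ⁻¹((n−0.375)/(n+0.25)) SDs in log space — and the
  log-mean is then solved so the truncated mean matches the target.
  Below-LOQ censoring ("Nd", LOQ 0.01 mg/kg) is applied to the lowest 5% of
  Cu/Ni/Pb draws in regions where the reference method reported it.
* **Correlation.**  A Gaussian copula imposes the inter-element
  correlations (Ca–Mg 0.97, Cr–Ni 0.90, the Fe cluster, the K
  associations).  Because the targets are stated on the raw concentration
  scale while the copula operates in a Gaussian layer under skewed
  marginals — and because the printed pairwise list is not jointly
  positive-definite (Ca–Mg 0.97 with Mg–P 0.31 but Ca–P unreported forces
  Ca–P > 0) — the generator calibrates the copula by damped fixed-point
  iteration against a large seeded Monte-Carlo draw, evaluated through the
  nearest-positive-definite projection, leaving unreported pairs
  unconstrained.  Moderate targets are then met closely; the strongest
  targets saturate at the maximal-dependence bound of the prescribed
  marginals (Ca–Mg reaches ≈0.93 against a comonotone ceiling of ≈0.97;
  Cr–Ni ≈0.8, limited by the Chilean marginal shapes), and the negative K
  pairs carry an irreducible contribution from the between-region mean
  structure alone.  This saturation is a property of the published summary
  statistics, not of the sampler.
* **Spectra.**  Beer–Lambert-style linear mixture: a fixed smooth baseline
  with broad water bands, two Gaussian bands per element centered at the
  wavelengths where regression coefficients for these elements peak (width
  10 nm), plus two sample-level interferents (water band level, a broad
  flavonoid band at 1530 nm).  Amplitudes (absorbance per mg/kg) are scaled
  to the pooled concentration SDs so that K, P and Zn are strong relative
  to the 0.004-absorbance channel noise while Cr, Ni, Cu and Pb are weak —
  reproducing the qualitative good-for-K/P/Zn, weaker-for-trace-metals
  pattern.  Each of the three replicates receives multiplicative scatter
  (log-SD 0.05), an additive offset (SD 0.02), a linear tilt (SD 0.02) and
  i.i.d. channel noise.
* **What it does not emulate.**  Real propolis spectra have far richer
  covariance (hundreds of overlapping organic bands, nonlinear
  particle-size effects, wavelength-dependent scatter).  The synthetic
  problem is consequently easier: the strong elements cross-validate at
  R² ≈ 0.99 rather than ≈0.95, and passing tests demonstrate correctness of
  the machinery and qualitative behavior, not real-world error levels.

## Numerical and design choices

* Coefficient extrema (`coefficient_extrema()`) report the wavelengths of
  the largest |β|.  On raw spectra the β peak of an element whose band sits
  in a crowded region (1480–1540 nm holds K, Ca, Mg, Ni bands plus the
  flavonoid interferent) is displaced by 10–20 nm as the model counteracts
  overlapping signals; second-derivative treatments suppress the broad
  interferents and restore band-center localization.  The band-recovery
  test therefore uses a second-derivative model of Zn, whose bands sit in
  the resolvable 1816/1976 nm region.
* Whether the 71-sample calibration used averaged triplicates or individual
  scans is ambiguous in routine practice; averaged spectra are used for
  both calibration and validation (`average_replicates()` is applied
  automatically by the pipeline).
* Below-LOQ reference cells are excluded from that element's calibration by
  default (substituting 0 or LOQ/2 is available) — exclusion avoids biasing
  the low-concentration elements.
* CV partitions are uniformly random given the seed; group sizes differ by
  at most one (n = 71, 6 groups → sizes 11/12).
* Test-suite problem sizes: the shared synthetic dataset is the default
  91-sample study; oracle-equivalence checks use twenty 30×50 problems; the
  H-mean check uses n = 500; the noise ladder uses three points.  The full
  default run (grid search over 20 treatments, 11 elements, elimination and
  external validation) completes in well under a minute.

## Known limitations

* The MPLS residual-scaling variant is validated by self-consistency and
  PLS1-equivalence, not against any commercial implementation.
* The copula calibration targets the pooled-cohort correlations; per-region
  correlation structure is not separately controlled.
* H elimination is single-pass by design; pathological mixtures where
  masking hides outliers behind inflated score variances would need robust
  PCA, which is out of scope.
* No JCAMP-DX or instrument-native formats; the CSV dialects documented in
  `read_spectra()`/`read_reference()` are the interchange formats.
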