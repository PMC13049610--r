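---
title: "High-resolution tissue elasticity mapping: models, generators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-resolution tissue elasticity mapping: models, generators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioelast)
```

## The measurement and the model

cardioelast analyses depth-sensing nanoindentation of soft tissue, the
technique used to map the stiffness of regenerating zebrafish heart
sections. A probe of known geometry is driven toward the sample while piezo
height $z$ and cantilever deflection $d$ (or force $F$) are recorded. After
the probe touches the sample at the contact point $z_c$, the indentation
depth is

$$\delta = (z - z_c) - (d - d_c),$$

i.e. piezo travel corrected for cantilever bending. For a spherical
indenter of radius $R$ on an elastic half-space, force and indentation obey
the Hertz law

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

with Young's modulus $E$ and Poisson ratio $\nu$ (0.5 for incompressible
soft tissue). This paraboloidal closed form is what vendor "Hertz–Sneddon
(sphere)" fitters implement; the exact Sneddon sphere solution
(`sneddon_force_sphere()`, parametric in the contact radius) is included
for sensitivity checks and differs by less than 5% at the shallow relative
depths relevant here ($\delta \lesssim 0.1\,R$).

Two instrument presets cover the two experimental regimes:

* `colloidal` — an AFM cantilever with a 10.8 µm polystyrene bead
  ($R = 5.4$ µm, $k = 0.2$ N/m), 16 nN setpoint, 6 µm ramp, quantitative-
  imaging grids over 20 × 20 µm fields on 100 µm fresh vibratome sections.
* `nanoindenter` — a rigid cono-spherical probe ($R = 100$ µm) for
  whole-organ indentation. The conical flank is ignored and the tip treated
  as a sphere, valid only because the fit is capped at indentation depths
  below 30 µm ($< R$, the sphere-dominated regime). This is a documented
  approximation, not an exact treatment of the cono-sphere.

No bottom-effect (finite thickness) correction is applied: the 100 µm
sections are much thicker than the ≤ 2.5 µm colloidal indentations. That
assumption would fail for thin samples or the deepest whole-organ indents.

## Fitting: contact point and modulus, jointly

The curve model is fitted by `hertz_fit()` in four stages.

1. **Baseline.** A least-squares line is fitted to the early extend
   segment (default 60% of samples). A trend diagnostic — the line is
   re-fitted on the window's first half and the tail residuals compared
   against propagated noise — detects windows that overshoot into contact;
   the window then shrinks (first to 40%, then geometrically) until its
   tail is clean. The residual SD of the final window is the per-curve
   force noise estimate.
2. **Coarse contact gate.** The first index where the smoothed corrected
   force (centred moving average, 11 samples) exceeds 5 × noise SD and
   stays above it for ≥ 10 samples. Curves that never cross the gate are
   flagged invalid (`no_contact`), never errored. The baseline is then
   re-fitted strictly before the detected contact and the gate re-run,
   iterating to a fixed point — this matters for soft curves whose
   pre-contact region is a small fraction of the ramp.
3. **Refinement.** For fixed $z_c$ the modulus has a closed-form solution
   (regression of $F$ on $\delta^{3/2}$ through the origin), so $z_c$ is
   refined by profiling: a linearised $F^{2/3}$-vs-$z$ extrapolation
   centres a grid of candidates (±15 samples), the residual sum of squares
   is evaluated on a fixed sample window for comparability, and a
   continuous golden-section polish between the bracketing grid points
   finishes the job. On noiseless curves this recovers the generator's
   modulus to better than $10^{-6}$ relative even for off-grid contact
   offsets; under the default 50 pN noise the median contact-point error
   is ~1 nm (tolerance 25 nm) and the median modulus error ~0.1%.
4. **Final slope with bending feedback.** The measured force enters the
   indentation through the bending correction, so regressing on measured
   $\delta^{3/2}$ suffers errors-in-variables attenuation. The final slope
   re-computes $\delta$ from the model-predicted force (three fixed-point
   iterations), which removes the small but systematic downward bias that
   a one-pass fit exhibits.

Curve QC follows explicit rules (the underlying experimental work reported
none): a fit is invalid if no contact is found, fewer than 50 in-contact
samples lie below the depth cap, the modulus is non-positive, or the
in-contact $R^2 < 0.8$. All thresholds are arguments. Invalid pixels are
excluded from all aggregation, never imputed; because the regional summary
is a median, censoring of the rare stiffest pixels (whose contact region is
shortest) has negligible effect.

## Aggregation

Maps are assembled per region and aggregated exactly as the stiffness-map
workflow prescribes: the region value $E_A$ is the **median over all valid
pixels pooled across that region's maps** (not a median of per-map
medians); the section summary is the arithmetic mean of the region medians,

$$E_{\mathrm{final}} = \mathrm{mean}(E_A, E_B, E_C),$$

one data point per heart section. Even pooled counts use the midpoint
convention. Cross-section summaries report mean ± SD of section-level
$E_{\mathrm{final}}$.

## What the synthetic generator emulates

Only regional summaries (mean ± SD in kPa) of the measured moduli are
available, never pixel-level raw data, so the generator is a two-level
log-normal chosen to make the pipeline's estimator well-posed:

* the section scale $E_s$ is log-normal, moment-matched so that its mean
  and SD equal the preset's printed values (e.g. cortical myocardium
  8.1 ± 2.9 kPa);
* pixel moduli within a section are log-normal with **median** $E_s$ and a
  fixed coefficient of variation (default 0.3).

Median-targeting at the pixel level makes the pooled pixel median an
unbiased estimator of $E_s$, hence the cross-section mean of
$E_{\mathrm{final}}$ an unbiased estimator of the preset mean — recovery of
the printed regional values is then a meaningful end-to-end test. The
pixel CV of 0.3 is a modelling choice (the violin plots of per-pixel values
are visibly broad but their width is not printed); it is configurable and
the recovery properties hold for CV ≤ 0.5. For the whole-organ study the
reported quantity is a grand mean of single indentations, for which
median-targeted within-heart values imply a small known upward offset of
$\sqrt{1+\mathrm{CV}^2}$-type magnitude (+4.4% at CV 0.3), well inside the
20% recovery band.

Force curves are generated by inverting the Hertz law self-consistently
with cantilever bending ($\delta + F(\delta)/k = z - z^*$ solved by
Newton's method per sample), adding an affine baseline tilt
(slope ~ $N(0, 10^{-5}\,\mathrm{N/m})$) and Gaussian force noise (default
SD 50 pN — a typical closed-loop AFM noise floor; both configurable and
zero-able for oracle tests). The ramp is truncated at the 16 nN setpoint;
samples softer than the setpoint within the ramp are returned truncated
(they still carry a metre of usable contact), and only degenerately soft
inputs (peak force below noise or 1% of setpoint) raise the
stiffness/setpoint-mismatch error. The retract segment mirrors extend, with
an optional adhesion dip used solely to verify that fitting consumes the
extend segment only. The generator does **not** emulate fluid drag,
thermal drift, cantilever tilt, viscoelastic hysteresis, or spatial
autocorrelation of tissue stiffness — so passing recovery tests demonstrate
correctness of the estimation chain under the stated noise model, not
robustness to every artefact of real force curves.

Sampling uses a 5 nm z-step (colloidal; 80 nm for the 100 µm ramp of the
nanoindenter), chosen so that the ≥ 50-in-contact-sample QC rule is
attainable even on the stiffest plausible pixels, avoiding a censoring bias
of the stiff tail.

Section phantoms emulate the stained-section geometry used to assign map
positions to regions: horizontal stripes for injury centre (DAPI++),
border (DAPI+) and myocardium with an embedded rectangular fibrin band
(DAPI−) of known length and width, nuclei placed by homogeneous Poisson
processes with per-region densities (defaults 0.008 / 0.003 / 0.0005 per
µm² for centre / border / fibrin, 0.004 for myocardium), and per-region
stiffness fields reusing the tissue presets. Phantoms record every mask as
ground truth; they do not simulate confocal point-spread functions, photon
noise, or real brightfield-to-confocal registration error (an affine
correspondence would be needed for real data and is out of scope).

## Region classification and morphometry

The regionalisation of real sections was done by eye from DAPI density;
the package makes that rule explicit and reproducible: nuclei densities are
computed in square windows and thresholded three ways
(DAPI− below `t_low` = 0.0012/µm², DAPI++ above `t_high` = 0.0055/µm²,
DAPI+ between). The classification window defaults to 75 µm: with Poisson
counting statistics at the default densities, 50 µm windows carry enough
counting noise to misclassify ~7% of interior windows, while 75 µm windows
keep phantom-truth agreement above 95%; density *measurement*
(`nuclei_density()`) itself remains window-agnostic and the conventional
50 µm sampling square is used in its examples.

Fibrin-band morphometry measures the deposit's length along its principal
axis (eigenvector of the pixel covariance) and averages three width
transects at 25/50/75% of the length — the transect positions are fixed
because the experimental protocol (three width measurements per section)
does not state where they were taken. Rotation tests hold to within about
one pixel of rasterisation error.

## The inference layer

The statistical tests mirror the study's spreadsheet/Prism conventions and
are implemented from first principles, with base R equivalents used as
independent cross-checks in the test suite only:

* `one_way_anova()` — classical fixed-effects decomposition, p from the F
  distribution, plus Tukey–Kramer pairwise comparisons. The studentized-
  range CDF is computed by nested Gauss–Legendre quadrature (128-node
  inner/outer rules, absolute accuracy ~1e-5, validated against published
  q-table entries).
* `variance_ratio_test()` — the spreadsheet-style heterogeneity screen:
  larger-over-smaller variance ratio, **two-tailed** p (capped at 1). The
  tail convention is not stated in the original protocol; two-tailed is
  the spreadsheet default and a one-tailed option is provided.
* `two_sample_t()` — pooled and Welch variants.

Reported p-values from the original study are not recovery targets: they
depend on unpublished raw data. What is checked instead is calibration
(type-I error 5% ± 1% under the null at 10⁴ simulations) and agreement
with the independent base R implementations.

## Problem sizes, seeds and determinism

Every stochastic function takes a seed; the pipeline draws per-section
sub-seeds from a single seeded stream via `sample.int` rather than an
arithmetic ladder of seeds, because linearly related seeds leave the first
Mersenne–Twister draws measurably correlated across sections and inflate
the across-section variance. Re-runs with the same configuration are
bit-identical.

The package's study-scale configuration is 24 sections × 3 maps × 16×16
curves per preset (the map grid is configurable up to the instrument's
native 32×32; 16×16 keeps a full preset recovery under ~1.5 minutes on one
CPU core while leaving the across-section sampling error — which dominates
— unchanged). Replicated sub-checks (heterogeneity detection rates,
condition ordering rates) are run on section-level draws from the
generator's scale distribution, which is the quantity those tests consume;
the full curve-level chain is exercised once per preset.

With 24 sections, the across-section standard error of the recovered mean
is $\mathrm{SD}/\sqrt{24}$ — for the high-variance fibrin presets
(9.0 ± 8, 4.3 ± 3 kPa) that is 14–18% of the mean, so recovery bands of
15–20% correspond to roughly ±1.1–1.4 SE: individual seeds can and
occasionally do land outside them even though the estimator itself is
unbiased to ~0.1% (verified against the generator's ground truth on every
preset).

## Known limitations

* Paraboloidal Hertz on a cono-spherical tip is only valid below 30 µm
  depth; no Oliver–Pharr unloading analysis, no viscoelastic models.
* The elastic half-space assumptions (small strain, no adhesion inside the
  fit range, homogeneity beneath the contact) are taken as given; real
  fibrin networks are porous and likely poroelastic on slower timescales.
* Phantoms share coordinates between "brightfield" and "confocal" layers;
  registration error of real image pairs is not modelled.
* The thresholds `t_low`/`t_high` are calibrated for the phantom's density
  regime; real DAPI densities in other tissues would need re-calibration.
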