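---
title: "Models and methods behind ocunano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ocunano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocunano)
```

ocunano implements the computational chain of a nanoparticle-in-thermogel
ocular delivery study: drug–carrier binding from dynamic dialysis, drug
mass balance from interrupted dialysis, Higuchi release kinetics,
DLS passive microrheology for mucoadhesion, confocal FWHM particle sizing,
and sparse-sampling noncompartmental pharmacokinetics. This vignette
records the models, the assumptions they rest on, the parameter defaults
and why they were chosen, and the limitations a user should keep in mind.

## Dynamic-dialysis binding model

Free drug equilibrates across a dialysis membrane into a sink; drug bound
reversibly to dissolved polymer or adsorbed on nanoparticle surfaces does
not. Under sink conditions the donor concentration then decays
log-linearly,

$$\ln\left(100\,\frac{C_d}{C_{d0}}\right) = \ln(100) - K_m F_f\, t,$$

with $K_m$ (h⁻¹) the membrane dialysis-rate constant and $F_f \in [0,1]$
the free drug fraction. The model assumes (i) binding equilibration much
faster than membrane transport, so $F_f$ is constant, and (ii) a true
sink. A plain-drug control has $F_f = 1$, so its fitted slope magnitude
*is* $K_m$; the bound ("interaction") percentage of a formulation is
$100(1 - F_f)$ with $F_f$ the slope ratio.

Numerical choices:

* **Free intercept.** The model pins the intercept at $\ln(100) = 4.605$,
  but the measured $C_{d0}$ carries the same assay noise as every other
  point; pinning the intercept makes the slope estimate hostage to a
  single measurement. `fit_log_linear()` therefore fits the intercept
  freely and reports its deviation from 4.605 as a diagnostic
  (on clean control data it stays within ±0.1).
* **Per-replicate fitting.** Replicated experiments are fitted one
  regression per replicate and summarized as mean ± SD of slopes, with a
  two-sided equal-variance Student's t against the control
  (`fit_binding_experiment()`). Pooled fitting — one regression through
  all replicates after per-replicate normalization — is available via
  `pooled = TRUE`; with balanced designs the two agree closely, but
  per-replicate fits are the default because they expose the
  between-replicate spread that the reported SD describes.
* **Clamping.** A slope ratio marginally above 1 means a formulation
  apparently dialysing faster than free drug, which can only be noise;
  it is clamped to $F_f = 1$ with a warning rather than an error, since
  the bound percentage is defined on [0, 100]. Slopes below $10^{-12}$
  in magnitude are treated as exactly zero so that numerically flat
  series calibrate as degenerate rather than as a vanishing rate.
* **Units.** Times are hours and slopes h⁻¹ throughout.

## Interrupted-dialysis mass balance

Stopping the dialysis at a set time and centrifuging the donor phase
splits the drug over three pools: nanoparticle matrix (NPM), dispersion
medium (DM) and receiving phase (RP). DM and RP are assayed; NPM is
obtained by closure (`100 − DM% − RP%`), mirroring the experiment, so the
three percentages always sum to exactly 100. A 2% relative mass-balance
tolerance absorbs assay error; within it the closure term may dip
marginally below zero. "The matrix fraction stayed at its initial value"
is operationalized as a range rule: over a caller-chosen window the NPM
percentage is *constant* when max − min ≤ 5 percentage points (the
experiment's initial value sits in a 15–18% band, so a 5-point range
threshold separates that band from the fade seen when particles start to
degrade). A decreasing RP series — cumulative transport running backwards
— raises a data-quality warning but not an error, since single-point assay
glitches are common and recoverable.

## Higuchi release kinetics

Diffusion-controlled release from a matrix follows
$Q(t) = k\sqrt{t} + b$ with a small intercept. `fit_higuchi()` is an OLS
fit of cumulative percent released on $\sqrt{t}$; `predict_release()`
clamps predictions to [0, 100].

**Time-unit convention.** Release slopes in this field are printed
sometimes per √h and sometimes per √min, and the two differ by a factor
$\sqrt{60} \approx 7.75$. ocunano defaults to **minutes** and records the
unit in every fit object: with the minutes convention a slope of 3.34
%/√min gives $3.34\sqrt{300} + b \approx 59\%$ released at 5 h, matching
the cumulative-release levels such slopes accompany, whereas the hours
reading ($3.34\sqrt{5} \approx 7.5\%$) cannot. Internal consistency of
slope and cumulative release decides the default; the unit remains
configurable.

Other choices: the release window is capped at 5 h by default (the
nanoparticles retain their payload far longer than that, so the gel is
the only kinetically active compartment in that window); fitted
intercepts outside the −0.99% … 2.88% band typical of diffusion-controlled
thermogel release are flagged (burst or lag), not failed; the slope
comparison uses the equal-variance t-test by default because n = 3
replicates per formulation is the norm (Welch is available).

## DLS passive microrheology

The instrument measures the intensity autocorrelation $g_2(\tau)$ of
tracer beads (500 nm polystyrene, radius $a$ = 250 nm by default)
embedded in the sample. The chain to viscoelastic spectra is the standard
one:

1. **Siegert relation**: $g_2 = 1 + \beta g_1^2$, so
   $g_1 = \sqrt{(g_2 - 1)/\beta}$ with coherence factor $\beta$.
2. **Gaussian displacements** (3-D convention):
   $g_1 = \exp(-q^2\,\mathrm{MSD}/6)$ with scattering vector
   $q = (4\pi n/\lambda)\sin(\theta/2)$.
3. **Mason's local power-law GSER**: at $\omega = 1/\tau$, with
   $\alpha(\omega)$ the smoothed local log–log slope of the MSD
   (clamped to [0, 1]),
   $$|G^*| = \frac{k_B T}{\pi a\, \mathrm{MSD}(1/\omega)\,
   \Gamma(1+\alpha)}, \quad G' = |G^*|\cos(\pi\alpha/2), \quad
   G'' = |G^*|\sin(\pi\alpha/2).$$

$\alpha = 1$ recovers a Newtonian fluid ($G' = 0$, $G'' = \eta\omega$,
$\eta^* = \eta$); $\alpha = 0$ an elastic plateau
($G' = k_BT/\pi a\delta^2$ for MSD plateau $\delta^2$). These closed
forms are the package's internal accuracy checks (both recovered to
better than 2% on simulated data).

Defaults and numerics: optics default to the 633 nm / $n$ = 1.33 / 173°
backscatter configuration of a Zetasizer-class instrument, all
overridable. Lags are retained while $g_2 - 1$ exceeds 3× the noise SD of
the long-lag baseline (last 10% of lags), with an absolute floor of
$10^{-6}\beta$ guarding against underflowed correlations on noiseless
input. $\alpha$ uses centered log–log finite differences, one-sided at
the ends, smoothed by a 5-point moving average. A $\beta$ set too low
makes $g_1^2$ exceed 1; the package clamps and warns, because the bias is
then uniform in $\ln g_1$ and the user should re-estimate $\beta$ rather
than trust rescaled spectra.

**Mucoadhesion call.** Mucoadhesive nanoparticles thicken a mucin
dispersion; `mucoadhesion_compare()` reports per-frequency
$\eta^*$ and $G'$ ratios of mix over plain mucin and classifies the mix
mucoadhesive when the median $\eta^*$ ratio exceeds 1.10. The 10%
threshold is an operational floor well above the ~2% round-trip accuracy
of the chain; absolute spectra depend on mixing proportions, so only
ratios on a common frequency grid are interpreted.

## Confocal FWHM sizing

An equatorial intensity profile across a fluorescent bead is fitted with
$A\exp(-(x-\mu)^2/2\sigma^2) + B$ (Levenberg–Marquardt, bounded); the
diameter is the FWHM $2\sqrt{2\ln 2}\,\sigma \approx 2.355\sigma$. The
fit is invariant to affine intensity changes and translation. What this
measures is the *apparent* size: a bead below the diffraction limit still
produces a PSF-wide spot, so apparent widths fold bead and PSF in
quadrature, and diameters below ~0.2 µm are flagged
`"diffraction-limited"` rather than suppressed. Unresolvable profiles
(no peak, non-convergence, fitted σ at or below the sampling step) raise
a classed error; `size_particles()` drops them with a warning.

`extract_profile()` traces the line through the image's intensity
centroid along the axis of larger second-moment extent, averaging a
3-pixel-wide band by default — the same wide-line trace used in
interactive image software, which suppresses single-pixel noise without
widening the profile.

**Bimodality rule.** Reports of aggregated populations list two size
modes; deciding bimodality by eye is not reproducible, so
`summarize_sizes()` uses the best two-means split of the sorted
diameters (each group ≥ 2) and accepts it when the between/within
variance ratio exceeds 4 — a Calinski–Harabasz-style threshold that
cleanly separates mode ratios ≥ 2 at realistic within-mode spreads while
rejecting unimodal noise. Modes are reported larger first, each as
mean ± SE (SD/√n).

## Sparse-sampling pharmacokinetics

Aqueous-humor sampling is destructive, so profiles are per-time summaries
(mean, SD, n) rather than per-animal curves. The exposure metric is the
linear trapezoidal AUC over 0–10 h; a zero concentration at t = 0 is
prepended when absent (topical instillation, no baseline drug;
configurable). Because the trapezoidal AUC is a linear combination
$\sum_i w_i \bar C_i$ of the per-time means, its variance follows by
propagation, $\mathrm{Var} = \sum_i w_i^2 s_i^2/n_i$ (Bailer's method),
with endpoint weights of half the adjacent interval and interior weights
of half the span of the two adjacent intervals. Two AUCs are compared
with $z = \Delta/\sqrt{V_a + V_b}$ against the standard normal; a t
reference with Satterthwaite degrees of freedom assembled from the
per-time contributions is available (`auc_contributions()`). With ~7 time
points × 6 eyes per profile the effective df is large, and the normal
test holds its nominal 5% level in simulation (observed 4–5% over 1000
null runs). Relative AUC is reported to 1 decimal, the conventional
precision for relative ocular bioavailability.

## Synthetic-data generators

The generators produce every input the pipeline reads, with ground truth
the analysis must recover — that is what the test suite leans on.

* `gen_dialysis_run()`: exponential decay at rate $K_m F_f$ with 2%
  multiplicative Gaussian noise by default (typical UV assay CV).
* `gen_release_curve()`: √t line plus 1 percentage point additive noise.
* `gen_pk_profile()`: zero-order input (gel-erosion-controlled
  absorption) with first-order elimination. The plateau
  $C_{ss} = k_{in}/k_{el}$ is reached by ~1 h when $k_{el} \approx 3$
  h⁻¹, reproducing the 1–10 h plateau shape of nanoparticle thermogels;
  6 eyes per time point and 15% relative SD match ocular PK practice.
  This model is a testing stand-in: the study data it emulates were never
  fitted to a compartmental model.
* `gen_dls_g2()`: Newtonian, single-relaxation Maxwell, or plateau MSD
  mapped through the exact forward chain, with additive $g_2$ noise.
* `gen_bead_image()`: isotropic Gaussian spots with
  $\sigma_{\mathrm{eff}}^2 = \sigma_{\mathrm{bead}}^2 +
  \sigma_{\mathrm{PSF}}^2$ on a constant background with additive
  Gaussian noise at a stated peak SNR. The recoverable truth is the
  *apparent* (PSF-convolved) diameter, exposed as an attribute. The
  noise is Gaussian rather than Poisson–Gaussian; at confocal photon
  counts this is the standard approximation, but images dominated by
  shot noise at very low counts are outside what the generator emulates.

All generators are deterministic under a fixed seed and restore the
session RNG state. What passing round-trip tests show is that the
analysis chain is self-consistent at realistic noise levels — not that
real instruments are free of the systematic effects the generators omit
(membrane fouling, multiple scattering, detector nonlinearity, PSF
asymmetry).

## Pipeline driver

`run_stage()` / `run_pipeline()` execute named stages from list or YAML
configs, write CSV artifacts plus a JSON summary per stage, and log the
package version, seed and config MD5. Inputs are validated before any
output is created, so a failing stage leaves no partial artifacts.
Identical config + seed reproduces byte-identical outputs.

## Problem sizes and test budget

The suites use desk-scale sizes chosen to make the statistical checks
sharp while keeping a full run in seconds-to-minutes: 10-point dialysis
grids over 0.5–5 h, 10-point release grids over 30–300 min, 60–80-lag
correlograms, 128-pixel bead images, 7-point PK grids with 6 eyes per
time; 200 seeds for binding parameter recovery and 1000 simulations for
each type-I-error check.

## Known limitations

* Binding inference assumes fast, reversible equilibrium; slowly
  equilibrating or saturable binding would bend the log-linear plot, and
  the r² diagnostic is the only guard.
* The Higuchi fit is empirical; no erosion/diffusion PDE of the gel is
  attempted, and extrapolation beyond the fitted window is clamped, not
  modelled.
* One-point microrheology near a particle's own length scale can be
  biased by local heterogeneity; no two-point correction is implemented,
  and no inertial or compressibility corrections are applied.
* Dose accounting in the formulation module accepts both the nominal
  concentration convention (total drug over final volume as stated for
  the preparations) and strict volume-based accounting, which differ by
  ~10% for the quaternary-ammonium route; the module does not decide
  between them.
* Whether reported AUC ± values are SDs or SEs of the AUC is not always
  stated in the literature; ocunano labels its own outputs explicitly
  (`sd_auc` is the propagated SD of the AUC estimator) and treats
  fixture values as SDs.
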