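---
title: "Methods and numerical choices in kleptophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical choices in kleptophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the modelling assumptions, default parameters and
numerical decisions behind `kleptophys`, in enough detail that every
computed number can be traced to a formula or a stated convention.

# Spectral side

## Calibration

Reflectance is computed per pixel and band as
$R = (S - D) / (W - D)$, where $S$ is the sample stack, $W$ the stack
recorded over a near-perfect diffuse white standard and $D$ the dark
stack. Pixels where $W - D \le 0$ carry no usable signal and are marked
undefined (`NA`), never silently zeroed. The identities $S=W \Rightarrow
R=1$, $S=D \Rightarrow R=0$, and invariance under a common additive
offset to $S$, $W$ and $D$ are enforced by tests.

## NDVI

$\mathrm{NDVI} = (R_\mathrm{NIR} - R_\mathrm{Red}) /
(R_\mathrm{NIR} + R_\mathrm{Red})$ with the bands nearest 752 nm (NIR)
and 676 nm (red, the chlorophyll *a* absorption maximum). Nearest-band
lookup breaks ties toward the lower wavelength. NDVI is invariant to a
positive rescaling of the cube, so it cancels residual illumination
structure that calibration leaves behind.

## Second-derivative spectra and δδ507

Spectra are optionally smoothed with a centred moving average
(`smooth_window`, default 5 bands; window 1 disables smoothing), then
differentiated with the central second difference
$(x_{i-1} - 2 x_i + x_{i+1}) / h^2$, where $h$ is the band spacing; the
result is a true second derivative in nm^-2^. Endpoint bands (and bands
consumed by the smoothing window) are undefined. The second difference
annihilates affine baselines exactly, which is the point: `dd507`, the
second-derivative amplitude at the band nearest 507 nm, responds to the
local curvature of the degradation-product absorption feature and not to
broadband brightness or tilt. For a quadratic input the operator is
exact; for a Gaussian dip it matches the analytic curvature to better
than 1% on a 0.5 nm grid — both are test oracles.

# Fluorescence side

`Fv/Fm = (Fm - F0)/Fm` from the dark-acclimated pair (default recorded
dark-acclimation time 30 min), and `ϕPSII = (F′m - F)/F′m` per actinic
step. Yield kernels mark pixels undefined when `F′m ≤ 0`, and flag
(rather than clip) `F > F′m`. Rapid light curves are built per pixel:
`ϕPSII` is computed pixel-wise and averaged over the region of interest,
then multiplied by PAR — averaging fluorescence first and dividing
afterwards is a different (and rejected) estimator, and a test pins the
distinction. The default nine-step PAR ladder is
3, 17, 30, 50, 78, 112, 152, 201, 254 µmol photons m^-2^ s^-1^. Steps
whose ROI is entirely undefined are dropped with a warning.

# Rapid-light-curve model

The exponential photoinhibition model is

$$\mathrm{rETR}(E) = \mathrm{rETR_s}\,
  \bigl(1 - e^{-\alpha E / \mathrm{rETR_s}}\bigr)\,
  e^{-\beta E / \mathrm{rETR_s}}$$

with light-limited slope $\alpha > 0$, photoinhibition slope
$\beta \ge 0$ and scale $\mathrm{rETR_s} > 0$. Derived quantities:

$$\mathrm{rETR_{max}} = \mathrm{rETR_s}
  \frac{\alpha}{\alpha+\beta}
  \left(\frac{\beta}{\alpha+\beta}\right)^{\beta/\alpha},
  \qquad E_k = \mathrm{rETR_{max}} / \alpha,$$

with the $0^0 \equiv 1$ limit at $\beta = 0$ (so
$\mathrm{rETR_{max}} = \mathrm{rETR_s}$). The curve's argmax is
$(\mathrm{rETR_s}/\alpha)\,\ln((\alpha+\beta)/\beta)$; tests verify the
closed form against direct numerical maximisation over 1000 random
parameter draws.

## Fitting

`fit_rlc()` uses Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with native box constraints
($\alpha, \mathrm{rETR_s} \ge 10^{-12}$, $\beta \ge 0$) rather than a
parameter-transformation wrapper: the box constraints deliver the same
bounds-respecting contract with a standard, well-tested optimizer.
Because $\beta$ and $\mathrm{rETR_s}$ become nearly collinear as
$\beta \to 0$ (the objective has a long flat valley, and a start exactly
at $\beta = 0$ gives a singular gradient), the fit is run from three
starting points — inhibited, uninhibited and high-scale — plus an
explicit two-parameter $\beta = 0$ submodel, keeping the lowest residual
sum of squares. Starting values are derived from the data: $\alpha_0$
from the through-origin least-squares slope of the three
lowest-irradiance points and $\mathrm{rETR_s}_0$ from the largest
observed rETR. Convergence failures are reported through the
`converged` flag, never as exceptions.

One estimation-theoretic caveat the tests respect: when the curve
maximum lies beyond the highest irradiance of the ladder,
$\mathrm{rETR_{max}}$ is an extrapolation and its sampling error is
inherently larger than for a maximum bracketed by the data. The
noisy-recovery acceptance checks therefore use truth parameters whose
argmax (~192) falls inside the nine-step ladder.

# Pigments

Pigment tables are tidy per-replicate mass tables
(`replicate, species, n_specimens, pigment, mass_ng`) with an explicit
basis flag; `per_cell()` divides by the specimen count exactly once
(re-application is rejected). Ratio indices are computed per replicate;
passing a single-row table of group means yields the ratio of means.
The de-epoxidation state and the DT/DD ratio obey
$\mathrm{DEPS} = \frac{r}{1+r}$ with $r = \mathrm{DT}/\mathrm{DD}$, an
identity under test. Which chromatogram classes count as degradation
products is configurable (`deg_members`); the default is phaeophytins
plus the two fucoxanthin-like degradation classes. Species comparisons
use exact Wilcoxon rank-sum tests — at 3 replicates per species the
smallest attainable two-sided p is 0.1, so no index can be flagged at
5%, a property the tests enumerate.

# Statistics

Welch's t carries its fractional Satterthwaite df; one-way ANOVA reports
the conventional $(k-1, N-k)$ df; Tukey HSD p-values come from the
studentized-range distribution and are condensed into compact letters by
insert–absorb. The Wilcoxon rank-sum test is exact for tie-free samples
with min $n \le 10$, otherwise normal-approximated with continuity and
tie correction. The assumption gate runs Bartlett and per-group
Shapiro–Wilk at 5% and recommends the nonparametric branch if either
fails (or when any group has $n < 3$). Proportion-valued data such as
Fv/Fm pass through the arcsine square-root transform before parametric
testing. Type-I calibration tests use designs whose *true* rejection
rate is ≈0.05 — discreteness makes the exact rank-sum rate depend
strongly on $n$ (0.041 at 6/6 but 0.0499 at 8/8).

# Synthetic generator

`make_scene()` renders a planispiral chamber arrangement (elliptical
chamber masks along an arc, youngest largest) over a dark background,
fills each chamber with diatom-type reflectance — Gaussian absorption
dips at 450, 585, 635 and 675 nm on a flat baseline, plus a 507 nm
degradation feature that grows as pigment is lost — and re-embeds the
reflectance into raw counts through a radially falling illumination
field, a wavelength-dependent lamp slope, a dark offset and Gaussian
shot noise. The stored ground truth includes the per-pixel noise-free
NDVI and its chamber means, so pipeline recovery can be asserted
exactly at zero noise.

Two presets encode the contrasting phenotypes: `"hg"` (9 chambers,
young-chamber NDVI 0.28, degradation gradient 0.12 per age step beyond
age 2, Fv/Fm 0.25, α 0.22, β 0.004, rETRs 40) and `"ew"` (11 chambers,
NDVI 0.40, no gradient, Fv/Fm 0.46, α 0.42, β 0.025, rETRs 28 —
low-light acclimated: steeper α, lower Ek). These preset values are free
modelling choices of this package, selected to produce the qualitative
patterns of interest (declining vs flat chamber profiles, roughly
twofold NDVI and Fv/Fm contrasts) at magnitudes convenient for testing;
they are not measurements. The generator's scope is deliberately
limited: no scattering model, no chamber overlap, no spectral
point-spread function, and fluorescence images are generated directly
from the programmed yield surface rather than from a photosystem model.

`make_fluorescence()` inverts the RLC model to a yield ladder
(`ϕ(E) = rETR(E)/E`), builds `F`/`F′m` pairs around a quenching decay
`exp(-E/600)`, and rejects parameter combinations implying yields
outside (0, 1).

Seeding uses `with_seed()` (restores the caller's RNG state) and
`sub_seed()` substreams, so every simulated specimen is independently
reproducible and generators never perturb an enclosing random stream.

# File formats

The available TIFF writer stores scaled integers in [0, 1] and has no
IEEE-float sample format, so `NaN`-coded undefined pixels are not
representable. The package's container is therefore: values affinely
mapped to [0, 1] (offset/scale recorded in a plain-text sidecar — JSON
for scalar images, CSV with wavelengths and state for cubes), a second
validity channel marking defined pixels, 32 bits per sample. The
encoding is lossless to ~2^-31^ of the data range, and round-trip
equality is under test for cubes, scalar images, label maps, polygon
maps, fluorescence sequences and all CSV tables.

# Problem sizes

Defaults are sized for a desk machine: 96 × 128 px scenes, a 201-band
400–800 nm grid (2 nm spacing), 6 specimens per preset in the simulated
pipeline. These are package choices, not instrument constants; all are
configurable through `run_config()`. The full test suite runs in about
a minute; the acceptance script in well under one minute.
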