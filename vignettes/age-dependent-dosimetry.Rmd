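---
title: "Age-dependent millimetre-wave dosimetry of near-surface tissues: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-dependent millimetre-wave dosimetry of near-surface tissues: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agederm)
```

## The problem

Above roughly 6 GHz the penetration depth of electromagnetic waves in soft
tissue shrinks to the millimetre scale, so nearly all of the power of an
impinging wave is deposited in skin. How much enters the body, where it is
dissipated, and how warm the tissue gets all depend on quantities that change
over a human lifetime: skin thickness, tissue water content (hence
permittivity and conductivity) and dermal blood flow. `agederm` assembles a
complete analytical chain for this question at 26 and 60 GHz — two bands used
by 5G systems — for a planar tissue model under normal-incidence plane-wave
exposure.

## Tissue model

The electromagnetic stack has four layers: stratum corneum (SC, 0.015 mm),
"ED" (viable epidermis + dermis treated as one layer, since both have nearly
the same water content; 1.396 mm for the reference adult), subcutaneous fat
(4 mm) and a semi-infinite muscle terminus. The thermal stack splits ED into
an unperfused viable epidermis and a perfused dermis, because only the dermis
carries blood vessels. Complex permittivities are tabulated at the two
working frequencies with the convention $\varepsilon^* = \varepsilon' -
j\varepsilon''$ under $e^{+j\omega t}$ time dependence.

One printed inconsistency had to be resolved: the source table lists the
viable epidermis as 1.396 mm atop a 0.060 mm dermis, which is anatomically
inverted and incompatible with the dermis holding the vasculature. The
default here uses a 0.060 mm viable epidermis over a dermis of
$h_{ED} - 0.060$ mm; `literal_table_split = TRUE` reproduces the literal
table reading for comparison. The split only affects where the perfusion
sink starts, not the electromagnetic solution.

## Age models

**Permittivity.** The real permittivity follows the Lichtenecker logarithmic
mixing rule between free water and the organic matrix,
$\varepsilon' = \varepsilon'^{\,\alpha}_W \varepsilon'^{\,1-\alpha}_T$, with
hydration rate $\alpha = \mathrm{TBW}\cdot\rho$. TBW (total body water) is
taken as litres per kilogram of body mass — numerically the water mass
fraction — and $\rho$ in g cm$^{-3}$, the only reading that keeps $\alpha$
dimensionless and in $(0,1)$. Eliminating the unknown matrix permittivity in
favour of the adult value gives

$$\varepsilon^* = \varepsilon_W'^{\frac{\alpha-\alpha_A}{1-\alpha_A}}\,
\varepsilon_A'^{\frac{1-\alpha}{1-\alpha_A}}
\left(1 - j\,\frac{\varepsilon''_A}{\varepsilon'_A}\right),$$

which leaves the loss tangent age-invariant (the ratio
$\sigma/(\varepsilon'\varepsilon_0)$ is treated as age-independent). The
model is applied to ED, fat and muscle; the thin SC keeps its adult
permittivity, as its state is dominated by environment rather than age.

Two inputs of this model are not published alongside the tissue table and are
therefore shipped as overridable named constants:

* $\varepsilon'_W$ — computed from a single-Debye model of liquid water at
  37 °C ($\varepsilon_s = 73.2$, $\varepsilon_\infty = 5.2$,
  $\tau = 6.5$ ps), giving about 37 at 26 GHz and 15 at 60 GHz. Any tabulated
  value can be passed instead.
* $\alpha_A$ — derived per tissue as $\mathrm{TBW}(35\,\mathrm{y})\cdot\rho$
  from the same TBW table used for other ages, with 35 y as the adult
  reference age (the observed plateau of the age trends lies between roughly
  25 and 40 y, and the reference skin thickness of 1.396 mm is quoted for a
  middle-aged man). This makes the age-35 stack reduce exactly to the adult
  stack, which the tests assert.

**Blood flow.** Dermal volumetric blood flow uses the resting forearm
regression $BF_D = 6.033\times10^{-4} - 3.55\times10^{-6}\,\mathrm{age}$
(s$^{-1}$), converted to the Pennes sink coefficient
$B = BF\,\rho_b C_b$ with $\rho_b = 1050$ kg m$^{-3}$ and
$C_b = 3617$ J kg$^{-1}$°C$^{-1}$. The regression is accepted for ages
0–120 y only.

**Thickness.** The age table sets the total ED thickness; the 0.015 mm SC is
constant with age.

## Electromagnetic solver

The stratified-media problem is solved with the cascade-reflection recursion
$R_i = (r_i + R_{i+1}e^{-2jk_{i+1}h_{i+1}})/(1 + r_iR_{i+1}e^{-2jk_{i+1}h_{i+1}})$,
terminated by $R = r$ at the deepest interface (the semi-infinite muscle
returns no reflection), followed by forward/backward amplitude propagation
from the incident field. Wavenumbers use the principal square root of
$\varepsilon^*$ (Re $n>0$, Im $n \le 0$), so the forward wave $e^{-jkz}$
decays with depth. The incident amplitude follows from the incident power
density as $|E_0^+| = \sqrt{2\eta_0\,\mathrm{IPD}}$ — the field
normalisation is not fixed by the power-budget quantities, and this is the
standard plane-wave reading.

Derived quantities:

* transmission coefficient $TC = 1 - |R_0|^2$ and absorbed power density
  $APD = TC\cdot \mathrm{IPD}$;
* $SAR(z) = \sigma|E(z)|^2/(2\rho)$ with $\sigma = 2\pi f\varepsilon_0
  \varepsilon''$ ($|E|$ a peak amplitude, hence the factor 2);
* per-layer absorbed power from differences of the time-averaged Poynting
  flux across each layer, the muscle taking the residual flux. A closed-form
  depth integration of $\sigma|E|^2/2$ provides an internal cross-check
  (agreement to $10^{-6}$ relative is asserted);
* peak SAR located by evaluating at every interface plus a dense in-layer
  grid (default 1 µm); in lossy layers the field decays monotonically so the
  peak sits at an interface — at the SC/ED boundary for the tissue stacks —
  but the grid guards against standing-wave maxima in low-loss layers.

The solver is verified against an independent 2×2 transfer-matrix oracle
(interface/propagation matrix products, implemented separately in the test
suite) on random 2–6 layer stacks, and against Fresnel closed forms at single
interfaces. Random-stack thicknesses in those tests are capped so the field
stays far above round-off at all sampled depths, keeping relative
comparisons meaningful.

## Thermal solver

The steady-state Pennes equation
$\lambda_i T_i'' = B_i(T_i - T_{blood}) - \rho_i\,SAR_i(z)$ is solved
analytically per layer: homogeneous solutions $e^{\pm m_i z}$ with
$m_i = \sqrt{B_i/\lambda_i}$ (a linear basis where $B_i = 0$), plus
particular solutions by undetermined coefficients on the complex-exponential
decomposition of the source — each layer's $\rho\,SAR$ is exactly a sum of
three exponentials ($e^{2\,\mathrm{Im}k\,z}$, $e^{-2\,\mathrm{Im}k\,z}$, and
an oscillatory cross term). When a source exponent falls within
$10^{-6}$ m$^{-1}$ of a homogeneous rate $m_i$ the resonant polynomial lift
$z e^{\gamma z}$ is used instead. Boundary conditions: temperature and heat
flux continuity at interfaces, $T \to T_{blood}$ at depth (the growing
exponential is excluded in the terminal layer), and convective exchange with
air at the surface.

The printed form of the surface condition has the sign of the temperature
gradient such that warm skin would *gain* heat from 20 °C air and the
unexposed baseline would exceed blood temperature; the package uses the
physical orientation $\lambda_1 T'(0) = h\,(T(0)-T_{air})$, which yields a
baseline surface temperature near 33–34 °C with $h = 7$ W m$^{-2}$°C$^{-1}$
(the heat-transfer coefficient is printed with first-power metre units; a
convective coefficient must be per m², the only dimensionally consistent
reading of the boundary equation).

The temperature elevation is obtained from the linear difference problem
(homogeneous boundary data, EM source), which equals the difference of two
absolute solves to solver precision; both routes are implemented and
cross-asserted. Because the whole problem is linear, the elevation scales
exactly with the incident power density.

An independent finite-difference reference (`fd_reference_solution`) uses a
conservative second-order scheme on a layer-aligned grid (per-layer uniform
spacing, harmonic-mean face conductivities), a second-order half-cell Robin
balance at the surface, and a Dirichlet condition at a truncation depth of
60–120 mm — far beyond the muscle decay length $\sqrt{\lambda/B}\approx
14$ mm. Grid convergence is second order (halving the step cuts the error
about fourfold); profile comparisons against the analytic solution use the
120 mm truncation so that the imposed bottom value does not dominate the
discrepancy.

## Synthetic age tables

The literature growth curves behind the age dependence (forearm skin
thickness, TBW, body weight) are not redistributable as data, so the package
generates tables with the same qualitative structure: anchors at ages
{5, 7, 12, 30, 35, 45, 65, 70} y, monotone (Fritsch–Carlson) shape-preserving
spline interpolation, and a per-age Gaussian inter-individual spread (default
10% coefficient of variation, truncated to physical bounds by rejection).
Only two anchor values are calibrated — skin thickness 1.396 mm and TBW 0.60
at the 35 y reference — and all others are synthetic placeholders: skin
thickens through youth and thins in late life back to roughly its childhood
value, TBW declines monotonically from 0.65 to 0.54. Consequently the
pipeline reproduces the *directional* findings (transmission coefficient and
absorbed power density rise with age, combined peak SAR falls, heating
rises, all within about ±20% from 5 to 70 y) but no numerical age-endpoint
value should be read as a reproduction of measured curves.

One sensitivity worth recording: with the default Debye water permittivity,
the permittivity-only peak SAR at 26 GHz *rises* mildly with age (the
improved air/skin match outweighs the conductivity drop), whereas the
combined sweep — where the thinner late-life skin also moves the standing
wave pattern — shows the decreasing peak SAR. How the permittivity-only
trend resolves depends on the steepness of the TBW decline, i.e. on exactly
the curve data the synthetic tables replace.

## Exposure levels and Monte Carlo

Incident power densities are either fixed (10 W m$^{-2}$, the whole-body
reference level) or resolved from the ICNIRP local-exposure limits
$55 f_G^{-0.177}$ (general public) and $275 f_G^{-0.177}$ (occupational),
valid for 6–300 GHz.

Monte Carlo uncertainty draws skin thickness, TBW and body weight from their
per-age Gaussians, recomputes TC, APD and peak SAR per trial (the peak-SAR
search uses a 20 µm grid there — the peak sits at the SC/ED interface, which
is always evaluated exactly), and reports the sample mean and the central
95% percentile interval (2.5th–97.5th), the interpretation adopted for a
"$P = 0.05$" uncertainty band. Body weight is sampled and recorded but does
not alter the outputs, since TBW already enters as a per-kilogram ratio.
Tests run at $10^4$ trials or fewer with fixed seeds; the analysis driver
defaults to 2000 trials per anchor age, at which the displayed digits of the
interval endpoints are stable.

## Problem sizes and tolerances

Default profile grids are 1 µm for SAR (2 µm in the profile exports), 400
points per layer for the temperature-peak search, finite-difference steps of
5 µm, and 100-depth random comparisons per oracle stack. Energy conservation
is asserted to $10^{-9}$, oracle field agreement to $10^{-8}$ relative,
bioheat boundary residuals to $10^{-9}$, analytic-vs-finite-difference peak
elevation to $10^{-3}$ °C, and dual-route elevation consistency to
$10^{-9}$ °C.

## Limitations

Normal incidence only; no polarisation, obliquity, curvature or surface
roughness; two tabulated frequencies rather than a dispersion model; no
transient heating or 6-minute averaging, and no spatial averaging over the
1/4 cm² apertures used by the guidelines; blood flow is treated as
exposure-independent (elevations stay a fraction of a degree); whole-body
TBW stands in for tissue-specific hydration in ED, fat and muscle alike.
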