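---
title: "Slab-model analysis of X-ray reflectivity from lipid monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slab-model analysis of X-ray reflectivity from lipid monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrrfit)
```

## The problem

A phospholipid Langmuir monolayer at the air--water interface -- here the
anionic lipid DMPS, clean or with cationic polylysine (PL-5, PL-12,
PL-200) adsorbed from the subphase -- is probed two ways:

* **Specular X-ray reflectivity** `R(qz)`, which encodes the laterally
  averaged electron-density profile `rho(z)` along the surface normal.
* **Langmuir compression**: the pressure--area isotherm `A(P)` and the
  Volta (contact) potential recorded during compression.

`xrrfit` implements the full analysis chain for both: forward modelling
and constrained fitting of `R(qz)` with two- and three-slab models,
electron-counting hydration of the lipid headgroups, the capillary-wave
roughness floor, and the empirical compression-law / potential-slope
analysis. A seeded synthetic-data generator emulates both measurement
types so every stage is testable by parameter recovery.

## The slab model and its rendering

The interface is a stack of `N` homogeneous slabs between air
(normalized density 0) and bulk water (normalized density 1; all
densities are stored relative to `rho_w = 0.333` e-/A^3, with
`integral_layer_density()` converting to absolute electron counts). For
the clean monolayer `N = 2`: an acyl-tail slab (`L1`, `rho1`) and a
headgroup slab (`L2`, `rho2`). Adsorbed polymer adds a third, thick,
dilute slab (`L3 ~ 100-170` A, `rho3 ~ 1.1-1.3`).

We use a depth-positive coordinate: `z = 0` at the tail--air boundary,
increasing into the subphase, interface `j` at `z_j = L_1 + ... + L_j`.
(Display conventions that put air at positive heights are a mirror
image.) Each interface is smeared by a Gaussian of width `sigma_j`,
giving the error-function profile

$$\rho(z) = \rho_{air} + \tfrac12 \sum_{j=0}^{N} (\rho_{j+1}-\rho_j)
  \left[1 + \mathrm{erf}\!\left(\frac{z - z_j}{\sigma_j\sqrt2}\right)\right].$$

This form has the physically required asymptotes (`rho_air` on the air
side, bulk water at depth) and conserves the integrated excess electron
density for any smearing width -- both are enforced as numerical
invariants in the test suite (to 1e-6).

```{r profile}
m <- dmps_interface_model("LC", "water")
m
prof <- density_profile(m)
range(prof$rho)
```

## The reflectivity forward model

Above the critical wavevector `qc = 4*sqrt(pi*r_e*rho_w)` (0.0217 1/A on
water; the matching critical angle at 0.175 A wavelength is 3.02e-4 rad,
i.e. 0.0173 degrees), the reflectivity of the smeared stack is computed
in the distorted-wave Born approximation as a slab sum:

$$R(q_z) = R_F(q_z)\,\Bigl|\sum_{j=0}^{N} (\rho_{j+1}-\rho_j)\,
  e^{-i\sqrt{q_z q_z^t}\,z_j}\, e^{-\sigma_j^2 q_z q_z^t/2}\Bigr|^2,
  \qquad q_z^t = \sqrt{q_z^2 - q_c^2},$$

with `R_F` the Fresnel curve of the ideally sharp interface and
normalized densities (the bulk-density normalization cancels). The
exponents are the standard effective-wavevector form: the `N = 0` case
collapses exactly to the Nevot--Croce result
`R_F * exp(-sigma^2 qz qzt)`, and for arbitrary 1--3 slab stacks the sum
agrees with an independent numerical oracle -- quadrature of the
gradient-integral master formula over the rendered profile -- to better
than 1% (both are test-suite properties). Below `qc` the Born sum is not
trusted and `R` is fixed at 1; fits exclude `qz < 1.2 qc` for the same
reason. The approximation degrades where `sigma * qz > 1`; fit reports
flag the fraction of datapoints beyond that band rather than silently
using them.

## Capillary-wave roughness

Thermal capillary waves set a floor on every interface width,

$$\sigma_0^2 = \frac{k_B T}{2\pi\gamma}\,\ln\frac{Q_{max}}{Q_{min}},
  \qquad Q_{max} = 2\pi/a,\quad Q_{min} = q_z^{max}\,\Delta\beta,$$

with `a ~ 10` A the intermolecular cutoff and `delta_beta` the detector
acceptance (0.023 degrees here). For water at 293 K this gives

```{r capillary}
capillary_width(72)                      # clean surface, gamma = 72 mN/m
capillary_width(50)                      # film-covered, lower tension
```

consistent with the 3.0--3.6 A roughnesses that tied-width fits return.
`Qmin` defaults to the maximum `qz` of the analyzed range (0.8 1/A)
times the detector acceptance, since the resolution enters only through
this logarithmic cutoff; no additional resolution convolution is
applied.

## Constrained fitting

`fit_reflectivity()` minimizes a weighted chi-square on `log10 R`
(the data span ~8 decades and the errors are fractional, 3--10%, so
decade-scale residuals weight the whole curve evenly), with
`sd(log10 R) = sigma_R / (R ln 10)` by error propagation. The optimizer
is bounded Levenberg--Marquardt (`minpack.lm`), restarted from 5
initial vectors perturbed by +/-20% (seeded) to reduce local-minimum
risk. Default boxes: `L` in [1, 300] A, lipid `rho/rho_w` in [0, 3],
polymer `rho/rho_w` in [1, 1.6], `sigma` in [1, 60] A; parameters
landing on a bound are flagged, as are parameter pairs with |r| > 0.95
in the correlation matrix (the `L3`--`sigma3` trade-off of thick diffuse
layers is the usual offender).

Constraint schemes mirror how such data are actually analyzed:

* `tie_all` -- one common lipid roughness `sigma0 = sigma1 = sigma2`
  (the capillary-wave picture); a three-slab model's deep polymer--water
  width `sigma3` stays free (`sigma3 >> sigma0` is checked post hoc, not
  imposed).
* `tie_inner` -- `sigma1 = sigma2` shared, `sigma0` free: the extra
  freedom needed when the high-angle tail (`qz > 0.5` 1/A) reveals
  intrinsic headgroup structure beyond capillary smearing.
  `compare_schemes()` fits both, compares the high-angle chi-square, and
  reports the intrinsic width `sqrt(sigma12^2 - sigma0^2)`.
* `fixed_tail` -- pins (`L1`, `rho1`) to the clean-monolayer packing for
  three-slab fits, the assumption that polymer adsorption leaves the
  acyl-chain packing unchanged.

95% confidence half-widths use the conventional single-parameter
chi-square criterion (`delta chi2 = 3.84`) after renormalizing
`chi2/dof` to 1. The default is the quadratic (Wald) form from the
Jacobian, with an explicit profile search available (`ci = "profile"`);
on these well-conditioned problems the two agree, which is itself a unit
test. Whether one renormalizes before applying the criterion is a
genuine ambiguity, so the unrenormalized half-widths are reported
alongside (`ci95_raw`).

```{r fit}
cur <- gen_reflectivity(dmps_interface_model("LC", "water"),
                        level = 0.05, seed = 42)
init <- interface_model(list(c(14, 1.1, 3), c(8, 1.4, 3)), sigma_bottom = 3)
fit_reflectivity(cur, init, constraint_scheme("tie_all"))
```

## Hydration by electron counting

With the slab parameters in hand, the headgroup hydration follows from
bookkeeping: the electrons under one molecule's footprint in the two
lipid slabs, minus the dry lipid's own electron count
(`Gamma = 391` for DMPS), in units of one water (`Gamma_w = 10`):

$$n = \frac{A\rho_1 L_1 + A\rho_2 L_2 - \Gamma}{\Gamma_w}.$$

```{r hydration}
hydration_number(70, tail = c(0.90, 12), head = c(1.25, 11))  # clean LE
suppressWarnings(
  hydration_number(40, tail = c(1.02, 16.1), head = c(2.1, 6.0)))  # PL-5 LC
```

The raw value is affine in every parameter and is reported as computed;
only the integer display clamps negatives to zero (with a warning),
since a small negative count is an exact electron budget within error.
Rounding is half-away-from-zero. Note the working areas `A ~ 70` and
`40` A^2 are themselves approximate: with `A = 40` the clean-LC count
evaluates to 2.5 waters against a quoted 3 +/- 1 -- inside the error
bar, but worth remembering when comparing rounded integers.

## Isotherm and Volta-potential analysis

The pressure--area isotherm in a single phase branch follows the
empirical elastic-shell law `A(P) = A0 + Ae * exp(-P/KP)`: a rigid core
`A0`, an elastic shell `Ae`, and a softness parameter `KP` (smaller
`KP` = more rigid). `fit_compression()` fits in area space (the law's
natural variable); the auxiliary goodness-of-fit scale `t0` is defined
here as the RMS *pressure* residual after inverting the fitted law --
it has pressure units and vanishes for a perfect fit, matching its role
as a small-is-good diagnostic. The law does not apply across the LE--LC
coexistence plateau; branch windows are user-specified pressure
intervals, and a slope-based plateau detector (|dP/dA| below 10% of its
low-pressure median) warns when a window straddles the transition.

The two-dimensional compression energy
`W(A) = integral of P dA from A to A(P_ref)` is accumulated by
trapezoidal quadrature, zero-referenced at `P_ref = 1` mN/m -- the same
point at which the Volta potential is zeroed. In the LE regime `dV` is
proportional to `W`; `volta_slope()` therefore fits a line *through the
origin* (both series share the reference zero, so a free intercept
would only absorb noise). `S` is reported in mV per mN/m A^2 and is
comparable only within this unit system.

```{r isotherm}
iso <- gen_isotherm(compression_model(59.8, 49.3, 8.1), seed = 1)
fit_compression(iso)
W <- compression_energy(iso)$W
volta_slope(W, gen_volta(0.132, W, seed = 2)$dV)
```

## What the synthetic generator does and does not emulate

`gen_reflectivity()` applies multiplicative Gaussian noise
(`R_obs = R(1 + eps)`, default level 5%, the midpoint of the 3--10%
counting-statistics band; draws are truncated to keep `R_obs > 0`) on a
200-point log-spaced grid over 0.02--0.8 1/A, recording
`sigma_R = level * R`. `gen_isotherm()` adds Gaussian area noise
(default 0.5 A^2) on a 1--22 mN/m grid; `gen_volta()` adds potential
noise (default 2 mV) to the exact line. All generators are pure
functions of (parameters, grid, seed).

They deliberately omit: scattering background (assumed already
subtracted), beam footprint and absorption, detector nonlinearity,
resolution convolution, off-specular/diffuse scattering from lateral
("mosaic") heterogeneity of the polymer layer, and the LE--LC
coexistence region of the isotherm. Passing recovery tests therefore
demonstrates that the estimators are correct and well-conditioned under
the stated noise model -- not that real beamline data are free of the
systematic effects above.

## Numerical choices and limitations

* Profile grids default to 0.1 A steps padded by `8 * max(sigma)`;
  asymptote and conservation checks run at 1e-6.
* Forward curves are capped at `R = 1`; model values below 1e-300 are
  floored before taking logarithms.
* Noiseless input curves carry `sigma_R = 0`; fitting then falls back
  to 5% relative weights with a message (weights only set the scale in
  that case).
* Recovery benchmarks run at desk scale: 200-point curves, 100
  isotherm replicates, 200-replicate interval-coverage loops. These
  sizes make the whole suite run in well under a minute while leaving
  the Monte Carlo error comfortably inside the tested tolerances.
* Fitting supports `N = 2` and `N = 3` stacks with the documented
  schemes; there is no dynamical (Parratt) recursion, no Bayesian
  sampling, no simultaneous multi-curve fitting, and no model selection
  beyond the two tied-roughness schemes.
* A thick diffuse polymer layer (`sigma3 ~ 20-40` A) pushes most of the
  measured `qz` range outside the `sigma qz <= 1` validity band; its
  parameters are effectively constrained by the low-`qz` region only,
  and the validity flag in the fit report makes that visible.
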