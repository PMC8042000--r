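---
title: "Optimality-based prediction of photosynthetic capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimality-based prediction of photosynthetic capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcmaxopt)
```

This vignette is the package's own account of the science it implements:
the optimality model for photosynthetic capacity, the climate drivers that
feed it, the statistical layer used to confront it with data, the nutrient
co-limitation model, and the synthetic-data generator. It also records the
numerical choices and the design decisions taken where the methodology was
genuinely open.

## The optimality model

### Least-cost regulation of $\chi$

During photosynthesis the intercellular CO$_2$ partial pressure $c_i$ falls
below the ambient $c_a$ because assimilation consumes CO$_2$ while stomata
resist its diffusion into the leaf. The ratio $\chi = c_i/c_a$ is assumed to
be regulated so that the summed unit costs of maintaining transpiration
capacity and carboxylation capacity are minimal. The cost-minimizing ratio
is

$$
\chi_{\mathrm{opt}} = \frac{\Gamma^*}{c_a}
  + \Bigl(1 - \frac{\Gamma^*}{c_a}\Bigr)\frac{\xi}{\xi + \sqrt{D}},
\qquad
\xi = \sqrt{\frac{\beta\,(K + \Gamma^*)}{1.6\,\eta^*}},
$$

where $\Gamma^*$ is the photorespiratory compensation point (Pa), $K$ the
effective Michaelis–Menten coefficient of Rubisco (Pa), $D$ the vapour
pressure deficit (Pa inside this equation; kPa at every I/O boundary of the
package), $\eta^*$ the viscosity of water relative to its 25 °C value, and
$\beta = 146$ the ratio of the unit costs of maintaining carboxylation
versus transpiration capacity. $K$ combines the twin affinities of Rubisco,
$K = K_C\,(1 + O/K_O)$, with $O$ the O$_2$ partial pressure. At $D = 0$ the
formula gives $\chi = 1$ exactly; as $D \to \infty$, $\chi \to
\Gamma^*/c_a$. Both limits, the monotone decline of $\chi$ with $D$ and its
rise with temperature, are asserted as tests.

### Coordination and the optimal capacity

Under typical daytime growth conditions, carboxylation and electron
transport are taken to be co-limiting ("strong form" of the coordination
hypothesis), which fixes the optimal Rubisco capacity at

$$
V_{\mathrm{cmax,opt}} = \varphi_0(T_g)\, I_{\mathrm{abs}}\,
  \frac{c_i + K}{c_i + 2\Gamma^*},
\qquad
\varphi_0 = \frac{0.352 + 0.021\,T_g - 3.4\times10^{-4}\,T_g^2}{8},
$$

with $I_{\mathrm{abs}}$ the absorbed photon flux (µmol m$^{-2}$ s$^{-1}$)
and $\varphi_0$ the intrinsic quantum efficiency following the temperature
dependence of electron transport in light-adapted leaves. The prediction is
standardized to 25 °C by dividing by the Arrhenius factor
$\exp[(\Delta H_a/R)(1/298.15 - 1/T_K)]$ for $V_{\mathrm{cmax}}$. Optimal
$V_{\mathrm{cmax}}$ is exactly proportional to light; optimal
$V_{\mathrm{cmax25}}$ *declines* with growth temperature because warm
leaves need less enzyme for the same catalytic output.

All kinetics inside the least-cost equation are evaluated at the *growth*
temperature $T_g$, not at an instantaneous leaf temperature: the theory
describes acclimation to the growth environment.

### Kinetic constants

The enzyme kinetics behind $\Gamma^*$, $K_C$, $K_O$ are the standard
in-vivo tobacco values, shipped as an overridable [`kinetic_params()`]
set:

| quantity | value at 25 °C | activation energy (J mol$^{-1}$) |
|---|---|---|
| $\Gamma^*$ | 42.75 µmol mol$^{-1}$ (4.332 Pa at sea level) | 37 830 |
| $K_C$ | 404.9 µmol mol$^{-1}$ (41.03 Pa) | 79 430 |
| $K_O$ | 278.4 mmol mol$^{-1}$ (28 209 Pa) | 36 380 |
| $V_{\mathrm{cmax}}$ | — | 65 330 |
| $J_{\mathrm{max}}$ | — | 43 900 |

Mole-fraction-tied quantities ($\Gamma^*$, $K_C$, $K_O$, $c_a$, $O$) scale
in direct proportion to atmospheric pressure; a property test verifies that
computing at elevation is identical to computing at sea level with every
partial pressure rescaled by $P(z)/P(0)$. Ambient CO$_2$ is a configuration
parameter as a mole fraction (default 400 µmol mol$^{-1}$, i.e. 40.53 Pa at
sea level), because a mole fraction is the portable quantity across years
and elevations. $O_2$ is 20.95% of dry air.

$\eta^*$ uses the compact Vogel-type correlation
$\eta(T) = 2.414\times10^{-5}\cdot 10^{247.8/(T_K - 140)}$ Pa s, valid for
liquid water (0–60 °C) and encapsulated behind `eta_star()` so an
alternative correlation can be swapped in. It gives
$\eta^*(10\,°C) = 1.459$.

### Climate elasticities

`climate_elasticities()` evaluates
$\partial \ln V_{\mathrm{cmax25}}/\partial \ln I$,
$\partial \ln V_{\mathrm{cmax25}}/\partial T_g$ and
$\partial \ln V_{\mathrm{cmax25}}/\partial \ln D$ by central finite
differences of the full chain, with relative steps of $10^{-5}$ on the log
axes and 0.01 K on temperature; if a difference step leaves the validity
domain of any component (e.g. the viscosity correlation), the step is
halved, up to ten times, before a numerical error is raised. The test suite
contains an independent, hand-derived analytic differentiation of the whole
chain; finite differences and analytic derivatives agree to $10^{-6}$ over
randomized environments. The light elasticity is exactly 1 by construction
(the chain is linear in $I_{\mathrm{abs}}$ and the 25 °C correction does
not involve light).

Two decisions deserve record:

* **Quantum-efficiency temperature term in the $T_g$ derivative.** Whether
  $\varphi_0$'s temperature dependence is carried through the temperature
  derivative is a genuine choice: the *prediction* always uses
  $\varphi_0(T_g)$, but the derivative can be taken holding $\varphi_0$
  fixed. At the median climate (PPFD 400 µmol m$^{-2}$ s$^{-1}$, $T_g$
  25 °C, $D$ 0.6 kPa, sea level) the chain gives $-0.0454$ K$^{-1}$ with
  $\varphi_0$ held fixed and $-0.0394$ K$^{-1}$ with it included. The fixed
  variant equals the widely reported theoretical coefficient of about
  $-0.05$ K$^{-1}$ at its printed precision and is the default
  (`include_phi0 = FALSE`); the flag exposes the other variant. Sensitivity
  to the assumed ambient CO$_2$ over 38–42 Pa moves this derivative by less
  than 0.001.
* **The vapour-pressure-deficit elasticity.** With the constants above, the
  chain evaluates $\partial \ln V_{\mathrm{cmax25}}/\partial \ln D =
  0.047$ at the median climate — noticeably below theoretical values of
  about 0.07 reported in the literature for the same climate. Both an
  independent symbolic differentiation and the finite differences agree on
  0.047, and the implementation's $\chi$ behaviour matches canonical
  published values (e.g. $\chi \approx 0.70$ at 20 °C, $D$ = 1 kPa, 400
  ppm), so the difference is attributable to variant kinetic-constant or
  parameterization choices upstream of published figures, not to an error
  in the chain; the value is reported as computed rather than calibrated
  toward the literature. The elasticity is insensitive to ambient CO$_2$ in
  38–42 Pa (< 0.001) and rises only to about 0.056 even at 4 000 m
  elevation.

## Climate drivers

The drivers $T_g$, PPFD, $D$ and $P_{\mathrm{atm}}$ come from monthly
climate via `growing_season_climate()`. Decisions, with rationale:

* **Daytime temperature.** The diurnal cycle is assumed sinusoidal with
  daylight hours from latitude and solar declination, giving the weight
  $w = 1/2 + \sqrt{1 - x^2}/(2\cos^{-1}x)$ on $T_{\max}$ with
  $x = -\tan\lambda\tan\delta$; $w \ge 1/2$ always, so the daytime mean
  never falls below the diurnal mean. At the equator or equinox this
  reduces to the closed form $T_{\max}(1/2 + 1/\pi) + T_{\min}(1/2 -
  1/\pi)$.
* **Declination.** No formula is canonical at monthly resolution; the
  package uses the standard annual harmonic $\delta = -23.45°\cos(2\pi(d +
  10)/365)$ at the mid-month day of year, swappable behind
  `solar_declination()`.
* **Polar months.** Under 24-hour daylight ($x \le -1$) the continuous
  limit of the weight is 1/2 (daytime mean = diurnal mean); polar-night
  months have no daytime and are excluded from the growing season.
* **Growing season.** Months with mean daily temperature $(T_{\max} +
  T_{\min})/2 > 0$ °C; only daily extremes are available, so their mean
  stands in for the daily mean. A site with no qualifying month is an
  explicit error, not a silent NA.
* **Vapour pressure deficit.** Magnus–Tetens saturation vapour pressure at
  the diurnal mean temperature minus the actual vapour pressure from
  specific humidity ($e_a = P_{\mathrm{atm}} W_{\mathrm{air}} R_v / (R_d +
  W_{\mathrm{air}} R_v)$, $W_{\mathrm{air}} = q/(1-q)$). Coarse humidity
  products occasionally imply supersaturation; negative $D$ is clamped to
  zero with a warning, and the aggregated $D$ is floored at 0.01 kPa
  (configurable) so its logarithm stays finite in regressions. Monthly $D$
  is computed first and then averaged (rather than averaging $e_s$ and
  $e_a$ first); the alternative ordering was noted and not taken, as the
  monthly statistic is the natural unit.
* **Pressure.** Standard-atmosphere lapse form $P = 101325(1 -
  0.0065z/288.15)^{g M_d/(R \cdot 0.0065)}$.
* **Radiation.** Shortwave (W m$^{-2}$) × 2.04 µmol J$^{-1}$ → PPFD.

Gridded-climate extraction and spatial interpolation are deliberately out
of scope; the module contract starts at per-site monthly climate.

## Trait standardization

`vcmax_one_point()` implements the one-point estimate
$V_{\mathrm{cmax}} \approx (A_{\mathrm{sat}} + R_d)(c_i + K)/(c_i -
\Gamma^*)$ and `vcmax_one_point_no_rd()` the variant with day respiration
assumed to be 1.5% of $V_{\mathrm{cmax}}$. The two are algebraically
consistent: setting $R_d = 0.015\,V_{\mathrm{cmax}}$ makes them identical,
a property verified to relative error $10^{-12}$ over randomized draws.
Kinetics use leaf temperature (the measurement condition), and $c_i$ must
be supplied per record — no imputation from $\chi$ is attempted.
`standardize_to_25()` divides by the Arrhenius factor at the measurement
temperature.

Site means (`aggregate_site_means()`) are two-stage by default —
individuals average into species-at-site, species averages into site means
— matching the definition of the analysis data points; plain pooling is
available behind `two_stage = FALSE`. Means are taken on the natural scale
and log-transformed only at regression time, because a mean of logs is not
the log of a mean and the two stages would otherwise not commute with the
transformation. Leaf nutrient contents are g m$^{-2}$ everywhere, with
mmol m$^{-2}$ converters at the boundary.

## The statistical layer

* Site-mean analysis: OLS of $\ln V_{\mathrm{cmax25}}$ on $\ln$ PPFD,
  $T_g$, $\ln D$ (`fit_site_mean()`).
* All-species analysis: the same fixed effects with *crossed* random
  intercepts for site and species (`fit_all_species()`), crossed rather
  than nested because species recur across sites. Estimation is REML via
  `lme4`. A singular random-effects fit falls back to OLS with a warning
  and a flag rather than failing.
* Variance components are reported as each random term's share of the
  site + species + residual variance — the variation left unexplained by
  the climate terms. Marginal and conditional $R^2$ are both reported; the
  marginal one is the value comparable with a site-mean OLS $R^2$.
* Fixed-effect p-values for mixed models use the large-sample normal
  approximation, consistent with reporting coefficients ±1 SE rather than
  denominator degrees of freedom.
* Model bias is $B = 100(V_{\mathrm{pred}} - V_{\mathrm{obs}})/
  V_{\mathrm{obs}}$ (%), scale-invariant by construction;
  `bias_regression()` regresses it on climate ($\ln$ PPFD, $T_g$, $\ln D$)
  or on leaf nutrients ($N_{\mathrm{area}}$ untransformed, $\ln
  P_{\mathrm{area}}$).
* Partial residuals adjust the response to hold all other predictors at
  their medians; regressing them on the predictor reproduces the fitted
  coefficient exactly (an algebraic identity for OLS, asserted in tests).
* Influential points are never dropped automatically;
  `influence_diagnostics()` exposes Cook's distances and
  `refit_without_influential()` refits without the top $k$ for sensitivity
  checks.
* Records with missing covariates are excluded listwise per regression,
  with counts surfaced as warnings.

## Nutrient co-limitation

`fit_minfunc()` fits $z = \mathrm{smoothmin}(a_N + b_N f(N_{\mathrm{area}}),
\; a_P + b_P f(P_{\mathrm{area}});\,k)$ by nonlinear least squares, where
the smooth minimum is the log-sum-exp formula
$Z = -(1/k)\ln(e^{-kx} + e^{-ky})$, evaluated max-shifted so it cannot
overflow. Its error against the hard minimum is bounded by $\ln 2 / k$,
attained at $x = y$ (property-tested over $10^5$ draws).

Decisions:

* **Limb form.** The functional form of the limbs is not fixed by the
  methodology the model comes from; the default here is linear in the
  natural log of each nutrient with $\ln V_{\mathrm{cmax25}}$ as response
  (log transformation being the natural choice for magnitude variables),
  with `limb_transform = "identity"` and `log_response = FALSE` available.
  Boundary-curve extraction (`classify_limitation()`) is generic — it
  solves equal limb predictions for $N_{\mathrm{area}}$ over the observed
  $P_{\mathrm{area}}$ range — so published boundary curves in other
  parameterizations (e.g. of the form $N = \ln(aP + b)$) are not expected
  to be reproduced term-for-term.
* **Sharpness.** $k$ is fixed (default 20) rather than estimated jointly:
  beyond the plateau ($k \gtrsim 10$) the likelihood is nearly flat in $k$,
  making joint estimation ill-conditioned. `k_sensitivity()` exposes the
  RSS-vs-$k$ profile so the plateau can be inspected.
* **Initialization.** Min-regression is multi-modal: a limb-wise linear
  fit pulled toward the upper envelope (intercept shifted by the 90th
  residual percentile) seeds the optimizer, plus deterministic jittered
  restarts from a golden-ratio sequence (no RNG involvement, so fits are
  reproducible regardless of seed state). BFGS with an analytic gradient,
  relative tolerance $10^{-12}$, at most 500 iterations; the best RSS
  across starts wins.
* **Identifiability.** A limb that is the argmin for fewer than two
  records cannot be estimated; it is flagged with a warning rather than
  silently returned.
* Standard errors come from the Gauss–Newton approximation (Jacobian of
  the smooth minimum); AICs are computed from the Gaussian log-likelihood
  on the same scale as the `lm` alternatives so
  `minfunc_model_comparison()` is a fair table.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of a global
leaf-trait compilation, not any particular dataset: a few hundred sites,
several species per site drawn from a shared pool sized so each species
occurs at about two sites (making the site × species design genuinely
crossed), wide climate ranges (PPFD 100–800 µmol m$^{-2}$ s$^{-1}$
log-uniform, $T_g$ 0–30 °C, $D$ 0.1–3 kPa log-uniform, elevation 0–4 500
m), and Gaussian effects on $\ln V_{\mathrm{cmax25}}$.

Parameter choices, made once:

* **Noise split.** Site, species and residual standard deviations default
  to a 50/22/28% split of the climate-unexplained variance — the split the
  mixed model is expected to recover — with a total unexplained variance of
  0.8 on the log scale, chosen so the site-mean climate regression explains
  a realistic one-third-ish of the variance rather than an optimistic
  majority.
* **Nutrient couplings.** Leaf N is a structural intercept (0.6 g m$^{-2}$)
  plus a metabolic component proportional to realized capacity (0.008 g
  m$^{-2}$ per µmol m$^{-2}$ s$^{-1}$, consistent with Rubisco-bound N
  stoichiometry) plus a soil-pH term (−0.25 g m$^{-2}$ per pH unit) and
  noise; leaf P follows soil total P on the log scale (slope 0.5). The
  coupling strengths are set so the soil signals are detectable at the
  scale of a hundred-site compilation — emulating analyses in which such
  couplings are resolvable — while staying within observed trait ranges.
* **Monthly climate emission.** The generator's contract is the
  growing-season aggregate, not weather realism: it emits twelve identical
  equatorial months (daylength weight exactly $1/2 + 1/\pi$) whose diurnal
  range and specific humidity are obtained by inverting the daytime
  temperature and vapour-pressure relations analytically. Passing the
  emitted table through `growing_season_climate()` reproduces the
  generating drivers to $10^{-6}$ (tested at machine precision in
  practice). Drawn $D$ is capped at 80% of saturation at the diurnal mean
  temperature so the humidity inversion stays physical — a mild, realistic
  $D$–$T$ coupling.
* **Reproducibility.** Every field draws from its own substream (fixed
  offsets from the configuration seed), so identical configurations
  reproduce identical bytes and adding a field never silently shifts
  existing draws.
* **Theory modes.** `theory_mode = "full"` (default) evaluates the
  nonlinear optimality chain per site; `"linearized"` generates from the
  tangent plane at the median climate, which is what makes the noise-free
  "OLS recovers the elasticities exactly" check well-posed — OLS on the
  full nonlinear surface estimates range-averaged, not point, derivatives.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: spatial autocorrelation of climate and soils,
phylogenetic structure among species effects, measurement-method mixtures
(every record is treated as an A–$c_i$-quality value), unbalanced sampling,
and real covariance between climate and soil fertility. Parameter-recovery
results on this generator demonstrate that the estimators are correct under
the assumed structure, not that the structure is true of any particular
compilation.

## Problem sizes and runtime choices

The default generator (200 sites × 8 species) is the size used for the
parameter-recovery checks; property tests use $10^3$–$10^5$ random draws;
sign/type-I/power simulations use 20–100 replicates at 100–200 observations
each. These sizes were chosen so the estimator properties they probe (2-SE
coverage, ±0.08 variance-fraction recovery, ±5-point limitation fractions)
are resolvable with comfortable margins.

## Known limitations

* No $J_{\mathrm{max}}$ optimality, no mesophyll conductance, no
  soil-moisture modifier of the least-cost balance.
* The vapour-pressure-deficit elasticity of the shipped constant set is
  0.047 at the median climate (see above); users comparing against
  literature values near 0.07 should expect that offset unless they swap
  in the variant constants that produce it.
* Mixed-model inference uses normal-approximation p-values; for small
  numbers of sites a Satterthwaite or bootstrap approach would be more
  conservative.
* The smooth-minimum model assumes exactly two candidate limiting
  nutrients and no three-way extension.
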