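# vcmaxopt

Optimality-based prediction of photosynthetic capacity from climate, with
the statistical machinery to confront those predictions with leaf-trait
data.

## The problem

The maximum rate of Rubisco carboxylation standardized to 25 °C
(V<sub>cmax25</sub>, µmol m⁻² s⁻¹) is the central photosynthetic capacity
parameter in terrestrial biosphere models, and the most expensive leaf trait
to measure. Eco-evolutionary optimality theory predicts it from physical
environment alone. `vcmaxopt` implements that prediction and everything
needed to test it against site-by-species leaf-trait compilations: the
growing-season climate drivers, one-point V<sub>cmax</sub> estimation,
site-mean and crossed mixed-model regressions, a model-bias statistic, and a
smooth-minimum model of nutrient (N–P) co-limitation. A seeded synthetic
data generator emulates the structure of a global dataset so the entire
pipeline runs and is validated without any data download.

## The model

Two hypotheses combine into the prediction:

**Least cost.** Stomata regulate the ratio χ = c<sub>i</sub>/c<sub>a</sub>
of intercellular to ambient CO₂ partial pressure so that the combined unit
costs of maintaining transpiration and carboxylation capacity are minimal:

    χ_opt = Γ*/c_a + (1 − Γ*/c_a) · ξ / (ξ + √D),   ξ = √[ β (K + Γ*) / (1.6 η*) ]

with Γ* the photorespiratory compensation point (Pa), K the effective
Michaelis–Menten coefficient of Rubisco, K = K_C (1 + O/K_O) (Pa), D the
vapour pressure deficit (Pa), η* the viscosity of water relative to 25 °C,
and β = 146 the carboxylation:transpiration unit-cost ratio.

**Coordination.** Under typical daytime growth conditions carboxylation and
electron transport are co-limiting, so the optimal capacity is

    V_cmax,opt = φ0(T_g) · I_abs · (c_i + K) / (c_i + 2Γ*)

with φ0 the intrinsic quantum efficiency (quadratic in growth temperature
T<sub>g</sub>) and I<sub>abs</sub> the absorbed photon flux. The result is
standardized to 25 °C by the Arrhenius factor for V<sub>cmax</sub>. Γ*,
K_C, K_O use in-vivo tobacco kinetics; all mole-fraction-tied quantities
scale with atmospheric pressure, hence elevation.

Nutrient co-limitation is modelled by the log-sum-exp smooth minimum

    Z = −(1/k) ln(e^(−k·x) + e^(−k·y)),

a differentiable stand-in for min(x, y) that allows least-squares fitting of
two nutrient "limbs" (x from leaf N, y from leaf P) and classification of
every record by its limiting nutrient.

## Worked example

```r
library(vcmaxopt)

env <- data.frame(ppfd = c(400, 650), tg_c = c(25, 12),
                  d_kpa = c(0.6, 0.9), elevation_m = c(0, 2500))
predict_vcmax(env)
#>   ppfd tg_c d_kpa elevation_m    chi ci_pa gammastar_pa  k_pa    phi0 vcmax vcmax25
#> 1  400   25   0.6           0 0.7972 32.31        4.332 71.90 0.08306 84.50    84.5
#> 2  650   12   0.9        2500 0.5654 16.89        1.592 17.33 0.06938 76.87   255.6
```

Row 1 is the median climate of the global compilation: χ ≈ 0.80 (well
inside the 0.5–0.9 range observed in C₃ plants) and a predicted capacity of
84.5 µmol m⁻² s⁻¹. Row 2, a cold high-elevation site, predicts a *higher*
V<sub>cmax25</sub>: more enzyme is needed for the same assimilation when it
is cold and CO₂ is scarce.

The climate sensitivities of the prediction at the median climate:

```r
climate_elasticities(make_fixture("table1_median"))
#>   elast_ln_ppfd elast_tg elast_ln_d
#> 1             1  -0.0454      0.047
```

Capacity is exactly proportional to light (elasticity 1), declines about
4.5% per kelvin of growth temperature, and rises with dryness.

The full pipeline on synthetic data with the default study conditions
(200 sites, 8 species per site, site/species/residual noise split
50/22/28%):

```r
sim <- generate_dataset(generator_config(seed = 1))
sm  <- aggregate_site_means(sim$leaf_obs, sim$soil)
fit <- fit_site_mean(dplyr::left_join(sm, sim$sites, by = "site_id"))
tidy(fit)
#>          term estimate std.error statistic  p.value
#> 1 (Intercept)  -0.1211    0.4624    -0.262 7.94e-01
#> 2     ln_ppfd   0.9735    0.0781    12.466 1.21e-26
#> 3        tg_c  -0.0404    0.0056    -7.220 1.12e-11
#> 4        ln_d   0.0921    0.0658     1.401 1.63e-01

glance(fit_all_species(sim_analysis_table(sim)))
#>   r.squared.marginal r.squared.conditional frac_site frac_species frac_residual nobs
#> 1              0.404                 0.835      0.52        0.202         0.278 1600
```

The site-mean regression recovers the generating climate responses within
two standard errors, and the crossed mixed model recovers the configured
variance split (52% site, 20% species against 50/22 configured).

Nutrient co-limitation on a deterministic demonstration fixture:

```r
mf <- fit_minfunc(make_fixture("minfunc_demo"), k = 50)
classify_limitation(mf)$fractions
#> N-limited P-limited
#>     0.225     0.775
autoplot(mf)   # (Parea, Narea) plane with the equal-limb boundary
```

## Scope

The package predicts V<sub>cmax</sub> only (no J<sub>max</sub> optimality),
assumes mesophyll conductance is non-limiting, and contains no soil-moisture
modifier. Gridded-climate extraction and spatial interpolation are out of
scope: per-site monthly climate is the input. See the methods vignette
(`vignettes/methods.Rmd`) for model details, parameter choices, and known
limitations.
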