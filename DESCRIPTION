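Package: vcmaxopt
Title: Optimality-Based Prediction of Photosynthetic Capacity from Climate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the maximum rate of Rubisco carboxylation standardized
    to 25 degrees C (Vcmax25) from growing-season climate using the least-cost
    hypothesis for the ratio of intercellular to ambient CO2 and the
    coordination hypothesis for photosynthetic capacity. Includes the
    supporting climate-driver calculations (daytime growth temperature,
    vapour pressure deficit from specific humidity, photon flux from
    shortwave radiation, barometric pressure), one-point estimation of Vcmax
    from light-saturated assimilation, Arrhenius standardization of kinetic
    rates, a statistical layer (site-mean ordinary least squares and crossed
    random-intercept mixed models, model bias, partial residuals), a
    smooth-minimum (log-sum-exp) regression model of nutrient co-limitation
    of Vcmax25 by leaf nitrogen and phosphorus, and a seeded synthetic-data
    generator emulating the structure of global leaf-trait compilations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
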