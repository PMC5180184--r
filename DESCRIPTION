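Package: gppiav
Title: Interannual Variability of Gross Primary Production via a
    SIF-Weighted Model Ensemble and the Budyko Framework
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse what controls the interannual variability
    (IAV) of terrestrial gross primary production (GPP). Builds a
    multi-model GPP ensemble weighted by each model's spatial agreement
    with satellite solar-induced chlorophyll fluorescence (SIF) within
    biomes; decomposes annual GPP into a long-term trend and detrended
    anomalies and attributes their variance to aridity classes;
    attributes GPP fluctuations to climate drivers with partial
    correlations; and links GPP IAV to precipitation through the Budyko
    evapotranspiration framework and the GPP-ET coupling slope (an
    ecosystem water-use-efficiency proxy). A seeded synthetic-world
    generator with known ground truth makes every stage testable at desk
    scale without external gridded products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
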