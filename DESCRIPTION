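Package: climdebt
Title: Climatic Debt of Plant Communities: Bioindication, Determinants and
    Bootstrapped PLS Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the climatic debt of plant communities (the gap
    between observed and floristically bioindicated temperature) and to infer
    its ecological determinants. Provides a weighted-averaging partial least
    squares transfer function with a random-forest residual stage for
    bioindication of temperature, soil pH and C:N from presence/absence
    assemblages; Schoener's D niche overlap and temporal distribution- and
    niche-conservatism indices; habitat, climate-context and human-pressure
    covariates on gridded landscapes; pairwise niche-differentiation
    competition indices with a community-assembly null model; a spatially
    thinned, per-year weighted, bootstrapped PLS regression with
    Bonferroni-based component selection, sign-test significance and variance
    partitioning; Moran's I correlograms; and a synthetic-data generator that
    plants known debts and covariate effects so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
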