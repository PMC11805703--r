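Package: twintraj
Title: Quantitative Genetics of Longitudinal BMI Trajectories in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the classical twin design applied to longitudinal body
    mass index (BMI) data. Simulates twin cohorts with a known additive-genetic
    and environmental architecture, extracts per-individual BMI trajectories
    (intercept and slope) from linear mixed-effects growth models, performs
    maximum-likelihood twin variance decomposition (ACE/ADE and submodels,
    sex-limitation variants, saturated-model assumption tests, profile-
    likelihood confidence intervals), fits multivariate Cholesky decompositions
    yielding genetic and environmental correlations, and correlates polygenic
    scores, residualized on genetic principal components, with phenotypes.
    All stages run full-information maximum likelihood over missingness
    patterns and are orchestrated by a seeded, manifest-logged pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
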