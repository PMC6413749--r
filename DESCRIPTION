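Package: dysregkit
Title: Physiological Dysregulation Scoring and Cross-Species Conservation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies physiological dysregulation in longitudinal biomarker
    cohorts as the Mahalanobis distance of an individual's biomarker profile
    from a configurable reference population, and tests whether homeostatic
    signatures are conserved across species. Provides cohort ingestion and
    filtering, per-marker normality-approximating transforms, reference
    population construction (species-self, cross-species, and balanced
    multispecies pools), dysregulation scoring with covariance conditioning,
    longitudinal mixed models of dysregulation on age and sex, counting-process
    Cox proportional-hazards models of mortality with age as the timescale,
    body-mass models, a phylogenetic matrix-correlation conservation test, and
    a multispecies synthetic cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    lme4,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
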