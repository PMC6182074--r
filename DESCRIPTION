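Package: spectreff
Title: Spectrum-Effect Relationship Modelling for Herbal Formulae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting bioactive components of multi-herb decoctions
    from LC-MS fingerprints: good-lattice-point mixture uniform designs on the
    simplex, retention-time/m-z tolerance matching of peaks to source botanical
    drugs, reciprocal-response and autoscaling preprocessing, single-response
    partial least-squares regression (NIPALS) with leave-one-out RMSECV latent
    variable selection, and ranking of candidate actives by their regression
    coefficients. Includes a synthetic-data generator with planted active
    compounds for end-to-end validation, and the hexa-herbal candidate formula
    (HHCF) case-study tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
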