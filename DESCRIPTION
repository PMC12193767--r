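Package: smilescw
Title: Monte Carlo QSAR Models from Optimal SMILES-Attribute Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds quantitative structure-activity relationship (QSAR)
    models for continuous endpoints such as acute aquatic toxicity (pLC50)
    directly from SMILES strings.  Molecules are decomposed into SMILES
    attributes (single SMILES atoms and pairs of neighbouring SMILES atoms);
    a Monte Carlo hill-climb assigns each attribute a correlation weight so
    that the summed weights (the optimal descriptor DCW) correlate with the
    endpoint, optionally steering the search with the index of ideality of
    correlation (IIC), the correlation intensity index (CII) or the
    coefficient of conformism of correlation prediction (CCCP) evaluated on
    a calibration subset.  Includes the four-subset split protocol (active
    training, passive training, calibration, validation), a
    statistical-defect applicability domain, multi-probe mechanistic
    interpretation of attributes, and a synthetic token-string data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
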