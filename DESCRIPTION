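Package: splicefactoR
Title: Predicting Splicing-Regulatory Activities of RNA-Binding Proteins
    from Sequence and Predicted Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature engineering and model selection for predicting the
    splicing-regulatory activity (log10 fold change in splicing outcome) of
    RNA-binding proteins from their amino-acid sequences and predicted
    one-dimensional structural profiles. Encodes each protein as a
    700-dimensional vector (amino-acid composition, dipeptide composition,
    composition-transition-distribution physicochemical descriptors, and
    secondary-structure-derived descriptors), ranks features by minimum
    redundancy-maximum relevance, refines the subset with a cross-validated
    forward search wrapped around partial least squares regression, and
    evaluates models by five-fold cross-validation with five regression
    metrics. Includes a synthetic-cohort generator with planted linear
    signals so that every stage can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
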