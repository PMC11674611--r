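Package: hbnet
Title: Hybrid Source-Space Brain Networks from Concurrent EEG-fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs hybrid brain networks in cortical source space from
    concurrently recorded EEG and fNIRS for emotion recognition. EEG is
    projected to an atlas-parcellated source space with a minimum norm
    estimate, directed effective connectivity among regions is measured with
    pairwise Granger causality on sliding windows, and a neurovascular
    coupling network is estimated by convolving normalized time-varying
    source power with the canonical hemodynamic response function and
    fitting measured fNIRS signals in a general linear model. Causal and
    coupling matrices are concatenated into hybrid network features and
    evaluated with repeated stratified cross-validation (linear SVM and
    KNN). Includes a synthetic coupled EEG/fNIRS trial generator with known
    ground-truth connectivity and coupling weights, readers and writers for
    delimited, EDF and MAT v5 trial layouts, and a scriptable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    class,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
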