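Package: aisacmmd
Title: Artificial Immune System Classification for Mixed and Incomplete Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prototype-generation classifier inspired by the adaptive immune
    system that natively handles tabular data mixing numeric and categorical
    attributes with missing values, using the Heterogeneous Euclidean-Overlap
    Metric (HEOM). Includes readers and writers for CSV and ARFF with explicit
    missing-value markers, dataset profiling (imbalance ratio), stratified
    hold-out splitting, balanced-accuracy evaluation via the confusion matrix,
    a 1-nearest-neighbour HEOM baseline, a Wilcoxon signed-rank comparison of
    classifiers with tied-rank and zero-difference conventions suited to small
    benchmark collections, a synthetic generator for mixed, incomplete and
    imbalanced datasets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
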