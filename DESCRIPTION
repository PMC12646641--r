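Package: svmeld
Title: Standardize, Merge and Benchmark Structural-Variant Callsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for multi-caller, multi-sample structural-variant (SV)
    analysis. Converts ambiguous VCF breakend (BND) records into canonical SV
    types (DEL, INV, DUP, TRA) by hierarchical classification of bracket
    orientation and mate pairing; merges callsets from multiple callers or
    samples by positional clustering with size-ratio and interval-Jaccard
    criteria, exposing flexible set operations (union, intersection,
    support thresholds, caller extraction, boolean expressions) and
    hierarchical genotype resolution; benchmarks callsets against truth sets
    (precision, recall, F1 overall and per SV type) and computes a truth-free
    trio Mendelian-violation rate. Includes a synthetic caller-VCF generator
    with planted ground truth and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
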