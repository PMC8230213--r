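Package: somaticCascade
Title: Tumor-Only Somatic Variant Filtration Cascade and Cohort
    Mutational Profiling
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a tumor-only somatic variant filtration and
    classification cascade for targeted cancer-panel sequencing (quality
    gating, common-variant exclusion, COSMIC/ICGC novelty classification,
    somatic/pathogenic routing, tissue-of-report specificity, and
    VAF-band germline inference), together with downstream cohort
    mutational-profiling statistics: binary gene-by-sample incidence
    matrices, per-gene summaries, clinicopathological stratification,
    Fisher/chi-square association, Pearson (phi) co-occurrence
    correlation, exact Hardy-Weinberg and minor-allele-frequency
    summaries, Bonferroni thresholding, and a from-formulas SKAT-O
    rare-variant association test with allele-frequency-dependent Beta
    weights. A count-exact synthetic cohort generator provides testable
    stand-ins for annotated panel data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, VariantAnnotation, Sequencing, SomaticMutation,
    StatisticalMethod
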