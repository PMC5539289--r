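Package: regblock
Title: Recurrent Promoter Mutation Blocks and Differential Transcription
    Factor Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative discovery of functional non-coding regulatory
    mutations from multi-patient somatic SNV calls. Clusters promoter SNVs
    into recurrent mutation blocks across patients, gates candidate target
    genes by tumor-versus-normal differential expression, scores
    transcription-factor binding affinity changes (delta-dbA) between
    reference and patient-specific alternative sequences with a biophysical
    position-weight-matrix occupancy model, and tests each factor's affinity
    shift against randomly generated background mutation blocks with a
    rank-sum test and Bonferroni correction. Includes a synthetic-cohort
    simulator with planted regulatory blocks for end-to-end validation, an
    expression-based filter for candidate factors, and a somatic
    hypermutation hotspot-motif (DGYW/WRCH) enrichment test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
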