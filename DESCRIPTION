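Package: serohap
Title: Mapping Blood-Group Genes from Serology, SNP Panels and Read Depth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the gene behind a serologically defined
    blood system and for DNA-based blood typing, built around the chicken I
    blood system and its RHCE gene. Implements pooled-DNA intensity-regression
    genome scans, individual case/control association with Bonferroni
    correction, candidate-variant contrast filtering, a 15-SNP RHCE haplotype
    panel with deletion-aware diplotype calling, serology-versus-haplotype
    concordance scoring, and structural-deletion detection from per-base read
    depth. A synthetic-data module generates every input the pipeline consumes
    with the statistical structure the analysis assumes, so the whole chain
    can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
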