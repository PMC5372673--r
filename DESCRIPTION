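Package: cytotoxQTL
Title: Cellular-Sensitivity QTL Mapping with MAF-Matched Enrichment and
    mRNA-Independent pQTL Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pharmacogenomic triangulation for cell-line cytotoxicity
    panels: dose-response IC50 phenotyping (constrained four-parameter
    logistic fits with interpolation fallback and censoring flags),
    genome-wide SNP association of minor-allele dosages with log2 IC50
    and with gene or protein expression, Hardy-Weinberg and allele
    frequency filtering, greedy LD pruning, permutation enrichment of
    expression and protein QTLs among drug-associated SNPs using minor
    allele frequency matched null sets with empirical p-values,
    mRNA-independent protein QTL discovery by residual regression, and
    FDR-controlled protein-phenotype association.  Includes a synthetic
    cohort generator with planted genetic effects for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    nortest,
    vcfR,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
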