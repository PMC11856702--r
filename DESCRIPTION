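Package: fermentrank
Title: Composite Fermentation Scoring and Comparative Genomics for Yeast Strains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates Saccharomyces cerevisiae strains for dough fermentation
    performance from phenotype panels (titratable acidity, specific volume,
    texture-profile indicators): prunes redundant indicators by Pearson
    correlation, builds an eigenvalue-weighted Cos2 composite score from a
    correlation-matrix PCA with Kaiser retention, ranks strains and selects
    extreme groups, contrasts the genotypes of the strongest versus weakest
    strains with a strict group-discriminating variant rule on multi-sample
    VCFs, and runs a hypergeometric overrepresentation test with
    Benjamini-Hochberg FDR over a user-supplied gene-to-term annotation.
    Includes synthetic generators with planted ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
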