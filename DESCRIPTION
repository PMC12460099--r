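Package: saltpanel
Title: Seedling-Stage Salt-Tolerance Evaluation and Association Genetics for
    Structured Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating seedling-stage salt tolerance in crop
    germplasm panels and mapping its genetic basis. Computes salt-tolerance
    indices (stress/control trait ratios), adjusts them across years and
    replicates with a REML mixed model (best linear unbiased estimates),
    condenses multiple traits into a composite membership-function D value
    via principal component analysis, and classifies accessions into
    tolerance groups by Ward clustering. On the genotype side it provides
    variant filtering, VanRaden kinship, genotype PCA, linkage-disequilibrium
    statistics and pruning, Weir-Cockerham FST and nucleotide diversity in
    sliding windows, a mixed-linear-model association scan with kinship and
    principal-component covariates, QTL interval construction with overlap
    merging, and haplotype-group phenotype contrasts. A synthetic-panel
    generator with population structure (Balding-Nichols allele frequencies)
    and a fully specified phenotype variance-component model provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
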