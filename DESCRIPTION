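Package: aimpanel
Title: Ancestry-Informative SNP Panel Design and Subspecies Assignment for Honey Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs reduced SNP panels for subspecies diagnosis in European honey
    bees (Apis mellifera) from pooled whole-genome allele frequencies, and assigns
    individual genotypes to subspecies with calibrated prediction probabilities and
    a rejection ("unassigned") threshold. Ancestry-informative markers are selected
    along two branches: per-SNP contributions to the significant principal components
    of a hierarchical (lineage-wise) PCA of minor-allele frequencies, and summed
    pairwise FST of every pool against all others under loose and stringent site
    filters with per-pool quotas. A hierarchical Balding-Nichols simulator generates
    pool frequencies and individual genotypes with subspecies-specific null-allele
    missingness, so the whole pipeline is testable without any sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    ranger,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
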