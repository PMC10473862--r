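Package: paleokin
Title: Kinship, Ploidy and Clinical Variant Screening for Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for shotgun-sequenced ancient-DNA cohorts genotyped on
    fixed SNP panels. Implements coverage-based per-chromosome copy-number
    estimation (genetic sex, sex-chromosome aneuploidies, autosomal trisomies)
    by z-scoring normalized coverage ratios against a set of reference
    genomes; pairwise-mismatch-rate kinship classification on pseudohaploid
    genotype matrices with block-jackknife uncertainty and relatedness
    networks; and a damage-aware screen of pileup evidence against clinical,
    pigmentation and mitochondrial variant panels. A synthetic-data generator
    (pedigree gene dropping, Poisson depth tables, deamination-damaged
    pileups) makes every method testable without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
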