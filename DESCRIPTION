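Package: recscan
Title: Family-Based Recessive Variant Discovery from Array and WGS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for mapping fully penetrant
    autosomal-recessive disease variants in small pedigrees, as used in
    canine retinal-degeneration genetics. Implements concordance mapping on
    SNP-array genotypes with haplotype-block region clustering and ranking,
    a staged hard-filter / known-variant / candidate-region / consequence /
    inheritance / deleteriousness prioritization cascade for WGS variant
    calls, codon-level consequence annotation with HGVS c. and p. names,
    allelic chi-square association, Mendelian segregation checking, and
    method-of-moments identity-by-descent estimation. Ships a pedigree
    gene-drop simulator that generates complete synthetic datasets (genome,
    gene models, array genotypes, VCF, truth set) so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
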