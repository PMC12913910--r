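Package: kelpgrowth
Title: Multi-Method Genotype-Phenotype Association for Small Wild Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for genotype-phenotype association in
    small natural populations genotyped by reduced-representation
    sequencing (ddRAD), motivated by field studies of kelp lamina
    elongation. Covers phenotype construction from hole-punch growth
    measurements, VCF filtering to a minor-allele dosage matrix,
    three independently implemented association engines (per-SNP linear
    model GWAS with Storey/Benjamini-Hochberg FDR control, ridge latent
    factor mixed models with genomic-inflation-factor calibration, and
    redundancy analysis with SNP-loading outlier detection),
    cross-method concordance with ddRADtag collapsing, a
    phenotype-permutation null for discovery counts, and polygenic score
    construction. Includes a synthetic-cohort generator with planted
    causal architecture so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
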