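Package: svkaryo
Title: Structural-Variant Karyotyping and Admixture Analysis for SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to take a multi-population SNP genotype matrix from VCF to
    (i) three-way admixture ancestry proportions and ternary hybrid classes,
    (ii) detection and genotyping of large non-recombining structural variants
    (SVs) from chromosome-wide and local PCA with southern-ancestry haplotype
    polarization, (iii) windowed differentiation and diversity landscapes
    (F_ST, pi, d_XY, heterozygosity, LD) with quantile-based SV flagging,
    (iv) an unphased cross-population extended haplotype homozygosity
    (XP-EHH) selection scan, and (v) neighbour-joining haplotype trees for SV
    regions. Includes a synthetic-data generator emulating three drifted
    lineages with an admixture gradient and megabase SV blocks, with ground
    truth for recovery testing, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
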