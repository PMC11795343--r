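Package: dustinct
Title: Molecular and Morphophysiological Distinctness Testing for Outbreeding Crop Varieties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for deciding whether varieties of an
    outbreeding crop (e.g., synthetic alfalfa cultivars) are distinct, from
    bulked-sample (pool-seq) SNP allele-frequency data and from spaced-plant
    trial data recorded in a randomized complete block design. Implements
    marker depth/missing-rate/MAF filtering with grid search, UPOV-style
    pairwise trait distinctness via Fisher's LSD, a PCA plus sequential
    per-axis ANOVA criterion, a PCA plus linear discriminant criterion,
    pairwise AMOVA on Nei's genetic distance with permutation or exhaustive
    p-values, UPGMA clustering with multiscale-bootstrap approximately
    unbiased (AU) cluster support, Mantel tests and classical MDS for
    cross-layer consistency, and a synthetic-data generator emulating
    cultivar allele frequencies, finite-plant bulks, sequencing read counts,
    and correlated traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    jsonlite,
    vegan,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
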