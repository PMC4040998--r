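Package: strucsel
Title: Selection on Duplicated and Horizontally Transferred Genes in Bacterial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure selection acting on structural variants segregating in
    closely related bacterial strains. Implements read-depth duplication calling from
    windowed coverage tracks (fractional multi-mapper counts, GC-bin median
    normalization, Poisson window tests, fold-coverage event filtering), identification
    of horizontally transferred genes from multi-species phyletic patterns, core-gene
    SNP classification (4-fold synonymous and nonsynonymous sites polarized against an
    outgroup, with recombination filters based on fixed:shared ratios, Hudson's Snn and
    synonymous-divergence percentiles), derived allele frequency spectra with a
    reference-genome ascertainment correction, Watterson/pi/Tajima's D diversity
    statistics generalized to gene-level variants, permutation and randomization tests
    comparing variant classes, and a four-bin estimate of the distribution of fitness
    effects from minor allele frequency spectra. A synthetic-data generator produces
    all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
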