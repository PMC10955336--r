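Package: phaselink
Title: Proband-Independent Linked-Read Haplotyping and Integrated
    Preimplantation Genetic Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs parental haplotypes around a pathogenic variant from
    barcoded linked-read fragment evidence (greedy minimum-error-correction
    assembly), signs the phased haplotypes as risk or non-risk by the allele
    they carry at the target site, and performs embryo linkage analysis for
    carrier status in preimplantation genetic testing for monogenic disease
    (PGT-M) without requiring a proband. Also implements the aneuploidy arm
    (PGT-A): per-window log2 read-count ratios segmented by circular binary
    segmentation with integer copy-number and mosaic-fraction calling,
    chromosome-level heterozygosity/B-allele-frequency Z scores for haploidy
    and triploidy, and runs-of-homozygosity detection by windowed
    heterozygosity ratio. A seeded synthetic-data engine generates linked-read
    fragments, MDA-style embryo genotypes with allele dropout, and
    overdispersed window counts so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
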