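Package: haplotrio
Title: Diploid Trio Genome Comparison, De Novo Mutation Rates and Sex-Chromosome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analyses for fully haplotype-resolved diploid trio
    genomes. Extracts and classifies the full spectrum of heterozygous
    differences (SNVs, indels, inversions, translocations, CNVs) between two
    haplotype assemblies, detects runs of homozygosity, filters pileup sites
    with a nucleotide-diversity statistic and partitions assembly errors into
    sequencing and polishing classes, estimates the trio de novo mutation rate
    with dual-reference cross-validation and callability correction,
    classifies scaffolds as X- or Y-linked from female/male coverage ratios
    with Hi-C interaction rescue and longest-rule de-collapse, and dates
    X-Y gametologue strata from synonymous divergence. A synthetic diploid
    trio generator with known truth supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
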