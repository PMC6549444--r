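Package: fawstrain
Title: Strain-Diagnostic Marker Analysis for Invasive Fall Armyworm Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of fall armyworm (Spodoptera frugiperda) amplicon
    sequences against a configurable panel of strain-diagnostic single
    nucleotide polymorphisms in the mitochondrial COI gene (COIB segment) and
    the Z-linked Tpi gene (exon 4 and intron 4 segments), including IUPAC
    ambiguity based heterozygote genotype resolution in males. Aggregates
    per-specimen calls into collection-level haplotype counts, converts
    specimen counts to chromosome-scale allele counts with a sex-linkage
    adjustment (x2 for male pheromone-trap collections, x1.5 for larval
    collections under a 1:1 sex ratio), computes haplotype and strain
    frequencies with across-collection means, runs regional Welch t-test
    comparisons, and reports mitochondrial-nuclear strain concordance.
    Also provides Tamura-Nei (TN93) distances with neighbor-joining tree
    construction and clade-composition reports for intron haplotypes, and a
    synthetic-data generator emulating field collections for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
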