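Package: curdscan
Title: Windowed Population-Genomic Scans for Domestication Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed nucleotide-diversity and Weir-Cockerham FST scans with
    top-percentile region merging, consensus-genotype identity-window
    introgression painting, gene-body genotype discrimination capacity,
    fourfold-degenerate-site classification, linkage-disequilibrium decay
    summaries, and delta-SNP-index bulked-segregant mapping with
    simulation-based confidence bands. Includes a seeded synthetic-data
    generator (toy genome, structured multi-group genotypes with planted
    divergent blocks, donor accessions with planted identical tracts, and F2
    bulk read counts) so the whole pipeline can be exercised end-to-end
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
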