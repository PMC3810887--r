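Package: palmine
Title: Microsatellite Locus Mining and Success-Rate Estimation from
    Enriched 454 Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing tetra-nucleotide microsatellite (SSR)
    markers from barcoded 454-style sequencing runs of motif-enriched
    genomic libraries. Reads FASTA/QUAL and FASTQ input, demultiplexes
    reads by species-specific MID barcodes, detects maximal perfect
    tandem repeats with motif canonicalization, applies a candidate
    filter cascade (flank length, flank homopolymers, read quality, a
    nearest-neighbour melting-temperature primer screen), and
    extrapolates potentially amplifiable loci (PALs) and per-species
    success rates from wet-lab SIPL/NTPP outcomes. Includes genotype
    table summaries (allele counts, observed/expected heterozygosity,
    exact Hardy-Weinberg tests, cross-amplification) and a synthetic
    read generator with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
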