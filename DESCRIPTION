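Package: ahepipe
Title: Anchored Hybrid Enrichment Phylogenomics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the bioinformatic workflow
    used in anchored hybrid enrichment (AHE) phylogenomics: probe and target
    design from multi-species locus alignments (exon-boundary detection with
    40-mers, high-copy 15-mer masking, uniform probe tiling), statistical
    merging of overlapping paired-end reads by a binomial overlap criterion,
    hybrid reference/de-novo assembly driven by spaced 20-mer seeds and exact
    60-mer extension, binomial consensus calling with IUPAC ambiguity codes
    and coverage-based soft-masking, contamination filtering, orthology
    clustering by shared-k-mer distance with a one-sequence-per-individual
    constraint, conservation-based alignment trimming, and partitioned
    supermatrix construction with a neighbor-joining sanity tree. A
    ground-truthed synthetic-data generator (species tree, anchor/flank locus
    evolution, paired FASTQ reads with quality scores, contaminants and
    paralogs) makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    seqinr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
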