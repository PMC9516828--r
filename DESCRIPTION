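Package: falsedup
Title: Detection, Classification and Impact Assessment of False
    Duplications in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects falsely duplicated sequence in haploid genome
    assemblies from cross-assembly and self alignments, confirms
    candidates with read-depth, assembly-gap and discordant read-pair
    evidence, classifies confirmed duplications as heterotype (both
    haplotypes of a heterozygous locus retained) or homotype (extra
    copies built from erroneous reads) using k-mer copy number and read
    multiplicity, quantifies the resulting gene mis-annotations (false
    gene, exon and chimeric gains), compares heterozygosity and sequence
    error rates between duplicated and correctly assembled regions with
    bootstrap tests, and scores correction between assembly versions.
    Includes a seeded diploid-genome simulator with ground truth so the
    whole pipeline is testable end to end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vcfR
LinkingTo: Rcpp
Config/testthat/edition: 3
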