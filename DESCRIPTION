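Package: tdnawalk
Title: T-DNA Insertion-Site Mapping from Genome-Walking Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transfer-DNA (T-DNA) insertion sites in plant genomes from
    paired-end genome-walking PCR amplicon libraries. Reads anchored in the
    transgene border are locally aligned to the vector, border-distal genomic
    fragments are recovered from soft-clipped and unmapped mates, matched
    against the (possibly polyploid) reference genome with a seed-and-extend
    nucleotide search under identity and e-value filters, and clustered into
    ranked candidate insertion loci with homeolog disambiguation and T-DNA
    orientation inference. Companion tools score palindromic hexamer
    walking-primer motifs for library design, genotype segregating progeny
    from two-PCR (anchored/flanking) zygosity assays, and simulate
    ground-truthed polyploid genomes, amplicon libraries and T2 populations
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
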