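Package: mlstyper
Title: Multi-Locus Sequence Typing from Short Reads by Targeted Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns multi-locus sequence types (MLST) to bacterial isolates directly
    from whole-genome-sequencing read sets, without whole-genome assembly. Reads are
    recruited per locus by the fraction of their length matching a reference allele
    exactly, assembled at several k-mer sizes with a targeted de Bruijn graph
    (greedy-overlap fallback), and alleles are called by exact full-length match
    against a PubMLST-style allele database; unmatched loci are reported as putative
    novel alleles with their trimmed sequence. Includes a sequence-type profile
    lookup, a synthetic benchmark generator (allele databases, profile tables,
    genomes, paired FASTQ reads), and the benchmark metrics used to evaluate typing
    tools: percentage of no-output, capability to identify correct alleles, and
    capability to identify new alleles under a leave-correct-allele-out protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
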