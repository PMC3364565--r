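Package: mutspectra
Title: Genome-Wide Mutation Spectrum Profiling for Microbial Mutagenesis
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the genome-wide mutation spectra
    produced by in vivo mutagenesis of haploid microorganisms, such as
    error-prone DNA polymerase delta mutator strains and EMS treatment of
    Saccharomyces cerevisiae.  Implements a variant filtering cascade with
    parental-strain subtraction and per-criterion rejection reasons,
    complementary-pooled transition/transversion spectrum classification,
    strand-aware gene-feature assignment (exon, intron, promoter,
    terminator, intergenic), codon-level amino-acid impact classification
    with BLOSUM62 conservative/nonconservative calls and a Gly/Pro + stop
    structure indicator, mutation-frequency and per-site rate estimation,
    and Luria-Delbruck fluctuation analysis (p0 and Ma-Sandri-Sarkar
    maximum likelihood).  A synthetic-data generator produces annotated
    toy genomes and mutagen-specific variant calls so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
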