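Package: isoval
Title: Validation and Differential Analysis of Long-Read Transcriptome Annotations
Version: 0.1.0
Authors@R: person("Open", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quality control of custom transcriptome annotations built
    from long-read (e.g. nanopore cDNA) sequencing. Classifies candidate novel
    transcripts against a reference annotation (cassette exons, novel donor and
    acceptor splice sites, novel junctions between known sites, novel start and
    termination sites, antisense duplicates), validates novel exons with
    orthogonal short-read coverage and splice junctions with split-read support,
    assigns coding status through a frame-conservation test and a CPAT-style
    logistic coding-potential model (Fickett TESTCODE and hexamer usage bias),
    checks novel start sites against CAGE peaks, catalogues alternative-splicing
    events between isoform pairs, performs TMM-normalised negative-binomial
    differential expression and isoform-fraction differential-usage testing, and
    estimates spike-in (sequin) limits of quantification by broken-stick
    regression. A fully deterministic synthetic-data generator provides ground
    truth for every stage, and a pipeline driver runs the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
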