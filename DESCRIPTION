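Package: progeval
Title: Proteogenomic Evaluation of Prokaryotic Structural Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating prokaryotic gene-calling quality with
    mass-spectrometry peptide evidence. Peptides are mapped onto a genome by
    exact, unique match against the six-frame translation; peptides falling
    wholly inside a gene call in the annotated strand and reading frame count
    as support, while conflicting peptides are classified into wrong, short
    and missed gene-calling errors with a two non-redundant peptide evidence
    threshold. Includes consensus statistics across multiple gene callers
    (identical calls, stop-consensus calls, unique calls), re-scoring of
    pseudogene calls refuted by confirming peptides, product-rule false
    discovery arithmetic, and a seeded synthetic-data generator that produces
    replicons, truth gene sets, caller-specific perturbed call sets and
    in-silico tryptic peptide evidence so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
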