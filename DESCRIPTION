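Package: earlinc
Title: Discovery and Prioritization of Long Non-Coding RNAs in the Inner Ear
    Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and prioritizing long non-coding RNAs
    (lncRNAs) from assembled transcriptomes of the mouse inner ear sensory
    epithelium. Implements PLAR-style transcript filtering (length,
    expression and coding-potential filters, the same-strand-intron
    exclusion) and the lincRNA/antisense/small-RNA-host taxonomy, novelty
    calling against a reference annotation, FPKM computation and
    tissue-specificity profiling against a multi-tissue panel, a
    differential-expression screen with Benjamini-Hochberg adjustment,
    cross-species orthology by sequence similarity and synteny with
    anchor-based interval liftover, and candidate prioritization by
    proximity to deafness genes and expression correlation. A synthetic-data
    generator with planted ground truth emulates every input the pipeline
    consumes, so the whole analysis can be exercised and validated end to
    end without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
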