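Package: noveltx
Title: Discovery and Classification of Unannotated Transcripts from RNA-Seq Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies transcripts assembled from RNA-seq that are absent from
    a reference annotation. Starting from a merged transcript assembly (GTF), a
    reference annotation, an ab initio predicted-gene track and per-transcript
    FPKM estimates with 95% confidence bounds, the pipeline isolates unknown
    intergenic transcripts (cuffcompare-style class codes, expression-CI
    filtering, predicted-locus subtraction), scores their protein-coding
    potential with two independent scorers (an alignment-free ORF/Fickett/
    hexamer logistic scorer and a CPC-style score, thresholded and
    intersected), curates tabular sequence-similarity hits under screening,
    manual-curation and synteny rules (including pseudogene inference from
    discordant adjacent gene context), annotates distance to the nearest
    annotated locus, and integrates the evidence into final categories (novel
    coding gene, amended gene/UTR, conserved lncRNA, lincRNA, pseudogene,
    ambiguous, inconsistent). A fully seeded synthetic-data generator plants
    transcripts of every category in a toy genome so the whole pipeline is
    testable offline.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
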