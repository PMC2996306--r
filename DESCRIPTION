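Package: txForge
Title: De Novo Transcriptome Assembly Curation, Polymorphism and Divergence Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and curating a de novo transcriptome from short
    paired-end RNA-seq reads when no reference genome is available. Implements
    read quality and poly-A filtering, an iterative multi-k de Bruijn unitig
    assembly ("assembly of assemblies"), target-based contig clustering around
    conspecific ESTs and heterospecific peptides, six-frame ORF extraction and
    evidence-based contig validation, reciprocal best-hit 1:1 orthology,
    short-nucleotide-discrepancy (SND) calling from read pileups with
    callable-length and read-depth corrected nucleotide diversity, RPKM
    expression summaries, and protein-divergence binning with chi-squared
    functional-category enrichment. A synthetic-data generator with full
    ground truth makes every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr
biocViews: Transcriptomics, Sequencing, Assembler, SNP, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
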