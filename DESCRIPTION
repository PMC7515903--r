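Package: silkforge
Title: Reconstruction, Annotation and Quantification of Repetitive Spider Silk Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with spidroin (spider silk protein) genes, which
    consist of non-repetitive N- and C-terminal domains flanking a long tandem
    repetitive domain that defeats conventional short-read assembly. Provides a
    seed-extension curation algorithm that screens short reads by exact
    large-k-mer match, extends seeds through position-weight-matrix consensus
    until repeat periodicity appears, and estimates repeat copy number from
    spanning long reads; domain and motif annotation with Kozak-context start
    codon selection and a signal-peptide hydropathy heuristic; amino-acid
    composition correlation clustering of repetitive domains; neighbor-joining
    bootstrap phylogenies of trimmed terminal domains with monophyly tests;
    in-silico Lys-C/trypsin digestion with emPAI protein quantification; and a
    synthetic-data generator (genes, paired short reads, noisy long reads,
    contig fixtures, peptide observations) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pheatmap,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
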