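Package: dinocodon
Title: Codon Usage Bias and Sex-Gene Inventory Analyses for Dinoflagellate
    Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative-genomic characterisation of codon usage
    and sex-associated gene repertoires in dinoflagellates and other
    microbial eukaryotes. Computes Wright's effective number of codons (Nc),
    positional GC-content, GC3s and relative synonymous codon usage (RSCU)
    for coding sequences; classifies genes by distance from the neutral
    Nc-GC3s expectation and from the GC12 = GC3 neutrality diagonal; runs
    correspondence analysis of RSCU matrices; screens proteomes for catalog
    genes with local alignment plus e-value and mutual-coverage filters,
    building presence/absence matrices; validates candidate homologs on
    gene trees by clade membership and terminal branch length; and scores
    GO-term over-representation with one-sided Fisher exact tests. Synthetic
    data generators with planted ground truth make the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phytools,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
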