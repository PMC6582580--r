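Package: gulotrace
Title: Detection of GULO Orthologs in Raw Genome Assemblies and
    L-Ascorbate Quantitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening raw (non-annotated) genome assemblies for
    L-gulonolactone oxidase (GULO) orthologs: a six-frame translated
    seeded local-alignment search with Karlin-Altschul statistics, merging
    of retrieved genomic regions sharing long exact overlaps, spliced CDS
    reconstruction by similarity-guided exon chaining under the canonical
    GT-AG splice rule, HWXK motif classification (HWAK diagnostic of
    animal GULO, HWGK of related VAO-family enzymes), per-species and
    per-lineage presence/absence calls with contamination screening, and
    Dollo-parsimony mapping of independent gene-loss events onto a
    species cladogram.  Companion utilities cover codon-aware alignment
    with column-support filtering, distance-tree ortholog placement with
    fungal-outgroup rooting, MCMC run diagnostics, and HPLC calibration-
    curve quantitation of L-ascorbate with ascorbate-oxidase identity
    confirmation.  A seeded synthetic-data generator plants multi-exon
    genes, fragmented and contaminated assemblies, and Gaussian-peak
    chromatograms with known ground truth, so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
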