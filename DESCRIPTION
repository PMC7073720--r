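Package: pgmine
Title: Mining Prostaglandin-Pathway Enzymes from Transcriptome Annotation Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-mining pipeline for locating prostaglandin-metabolism enzymes
    in assembled transcriptomes annotated against Swiss-Prot, in the style of
    the MMETSP (Marine Microbial Eukaryote Transcriptome Sequencing Project)
    file bundles. Reads per-transcriptome bundles (nucleotide and peptide
    FASTA, GFF3/TSV annotation tables, per-contig read counts, assembly
    statistics), queries annotation descriptions by keyword, canonicalizes
    hits against a nine-enzyme controlled vocabulary, collapses redundant
    transcripts by greedy incremental amino-acid identity clustering
    (CD-Hit-style), quantifies per-function expression by FPKM summation, and
    summarizes presence/occurrence across species, transcriptomes and growth
    conditions. Includes a synthetic-bundle generator with planted pathway
    genes, redundant copies at controlled identity, decoy annotations and
    overdispersed read counts, so that every pipeline stage is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
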