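Package: hsta
Title: Hidden-State Taxonomic Assignment for coxI Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Taxonomic assignment of animal barcode (coxI) amplicon reads
    without OTU clustering. Builds per-taxon nucleotide profile hidden
    Markov models from protein-guided codon back-alignments, scores reads
    with a local-mode forward algorithm, and classifies each read as Good,
    Ambiguous or Unclassified using a log-Bayes-Factor rule over competing
    profile scores. Also provides a GC-content/site-diversity regression
    diagnostic for sequencing error structure, mock-community evaluation
    statistics (detection ratios, biomass correlations, species-pair read
    ratios), and a biomass-weighted mock-community read simulator with a
    GC-dependent error model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
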