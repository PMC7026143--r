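Package: genedup
Title: Gene Duplication Inference from Codon Substitution Rates and
    Gene-Tree Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring recurrent gene duplication in small gene
    families, motivated by nuclear-encoded plastid genes such as rpl32.
    Implements Nei-Gojobori (1986) pairwise dN/dS with pathway averaging
    and Jukes-Cantor correction, Goldman-Yang (1994) codon models with
    F3x4 frequencies, Felsenstein pruning likelihoods and branch-model
    likelihood-ratio tests, Gaussian-mixture peak detection on synonymous
    distance (Ks) distributions with BIC model selection, Zmasek-Eddy
    gene-tree/species-tree reconciliation with duplication age classes,
    functional-group rate-acceleration tests, paralog summary tables, and
    homopolymer frameshift/heteroplasmy classification of clone sets. A
    truth-emitting simulator of duplication/loss histories and GY94 codon
    evolution makes every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
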