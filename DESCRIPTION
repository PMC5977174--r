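Package: fasterx
Title: Selection Analyses for X-Linked and Autosomal Genes on Young Sex
    Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-substitution-model analyses of selective pressure for
    comparing X-linked and autosomal genes in a six-species phylogeny with a
    dioecious foreground clade. Implements a 61-state codon likelihood engine
    (one-ratio, two-ratio branch, M1a/M2a and M7/M8 site models, branch-site
    model A and its fixed-omega null) with likelihood ratio tests, pairwise
    dN/dS, and marginal ancestral reconstruction; a four-fold-degenerate-site
    supermatrix and Shimodaira-Hasegawa gene-tree conflict filter; codon usage
    bias statistics (effective number of codons, frequency of optimal codons)
    and preferred/unpreferred codon change counting; silent-site nucleotide
    diversity and Tajima's D from diploid IUPAC-coded sequences; and a
    synthetic data generator emulating the study design, including a
    sex-specific-ploidy coalescent for X versus autosomal polymorphism.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
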