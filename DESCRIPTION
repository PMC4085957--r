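Package: ccmphylo
Title: Molecular Evolution of Carbon-Concentrating-Mechanism Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the co-option of genes into C4 and CAM
    photosynthesis within multigene families. Implements Goldman-Yang
    codon substitution models with site and branch-site mixtures (M0,
    M1a, M2a, branch-site model A), maximum-likelihood fitting,
    likelihood-ratio tests and AIC ranking of a-priori foreground-branch
    hypotheses; likelihood-based placement of transcriptome contigs on a
    reference gene-family tree with reads-per-million (rpm) aggregation
    by gene lineage; diagnostic-residue screening against a reference
    protein numbering (e.g. the Ser780 marker of C4/CAM-recruited PEPC);
    and forward simulators for codon alignments, nested-lineage
    reference panels and diel/drought expression experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
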