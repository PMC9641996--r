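Package: gerrophylo
Title: Ortholog Supermatrix Construction and Ancestral Character State
    Reconstruction for Transcriptome-Based Phylogenomics
Version: 0.1.0
Authors@R:
    person("Gerrophylo", "Developers", email = "dev@gerrophylo.org",
           role = c("aut", "cre"))
Description: A desk-scale phylogenomic toolkit for semi-aquatic bug
    (Gerromorpha) style transcriptome studies. Builds filtered ortholog
    supermatrices from transcript clusters and pairwise-hit tables
    (contaminant flagging, redundancy reduction, species-coverage
    filtering, representative-transcript selection with chimeric-cluster
    splitting, conserved-block concatenation at codon positions 1+2) and
    screens alignments with matched-pairs symmetry tests of the
    stationarity/reversibility/homogeneity (SRH) conditions (Bowker,
    Stuart, internal symmetry). Downstream, it fits Mk models (ER, SYM,
    ARD) with AICc and likelihood-ratio model choice, computes marginal
    ancestral state probabilities, samples stochastic character maps,
    performs Sankoff parsimony, counts independent character-state
    transitions, and estimates Pagel's lambda and Brownian-motion
    ancestral states with variances and confidence intervals. A
    synthetic-data generator with recorded ground truth (trees, trait
    histories, planted chimeras and contaminants, clade compositional
    shifts) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
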