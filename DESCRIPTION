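Package: spliceCoev
Title: Correlated Evolution of Splice-Site Positions on a Star Phylogeny
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the joint evolution of nucleotide positions
    within donor and acceptor splice sites across three mammalian genomes
    (human, mouse, dog) under a trifurcating star phylogeny. Per-position
    4x4 branch substitution matrices and ancestral nucleotide vectors are
    estimated from orthologous site triples by constrained least squares;
    ancestral posteriors, position-weight-matrix strengths, neutral-control
    expectations and the relative strength change omega quantify selection
    on consensus adherence. Monte-Carlo simulation under position-independent
    evolution, position-by-position strength covariance matrices with
    bootstrap significance, polypyrimidine-tract dinucleotide statistics
    with a first-order Markov shuffling control, and a synthetic-data
    generator with known ground truth complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Phylogenetics, SequenceMatching, Software
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods-SpliceSiteSet.R'
    'sites_io.R'
    'substitution_model.R'
    'ancestral_strength.R'
    'evolution_sim.R'
    'covariance_analysis.R'
    'ppt_dinucleotide.R'
    'synthetic_data.R'
    'pipeline.R'
    'spliceCoev-package.R'
    'stats_boot.R'
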