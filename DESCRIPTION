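Package: mixscan
Title: Locus-Specific Mixture Proportions Along the Genome from Population Allele Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers locus-specific mixture (migration) proportions along a genome
    from population allele counts, given a fixed admixture-graph topology. Allele
    frequency drift along the graph is modelled as Brownian motion on the arcsine
    scale, giving Gaussian marginal likelihoods of transformed sample frequencies;
    a hidden Markov model over discretized per-edge migration rates, with
    distance-scaled ladder or attractor transition kernels, captures linkage.
    Parameters are learned by an empirical Bayes scheme combining Gaussian-mixture
    initialization, least-squares coercion onto the graph, and SQUAREM-accelerated
    Baum-Welch; per-locus posterior mean rates and false-discovery scores for
    excess or dearth of introgression are reported. A model-faithful simulator
    generates allele-count datasets with constant, peak-block or Markov migration
    tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: PopulationGenetics, HiddenMarkovModel, SNP
Config/testthat/edition: 3
RoxygenNote: 7.3.3
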