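Package: ddclone
Title: Joint Inference of Tumour Clonal Structure from Bulk and Single-Cell Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters somatic point mutations and estimates their cellular
    prevalences from bulk allele counts, using single-cell genotype
    co-occurrence as a Bayesian non-parametric prior. Mutations are customers
    in a distance-dependent Chinese restaurant process whose link
    probabilities decay with the Jaccard distance between loci in a binary
    genotype-by-locus matrix; bulk variant read counts enter through a
    copy-number-aware beta-binomial likelihood marginalized over locus
    genotype states. Inference is by Gibbs sampling over customer links with
    cached Griddy Gibbs resampling of per-cluster prevalences. Includes
    simulators for clone genotypes on a phylogeny with Dirichlet-multinomial
    cell assortment bias, doublets and allelic dropout, plus V-measure and
    prevalence-error benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
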