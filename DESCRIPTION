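Package: paleowgd
Title: Detection and Placement of Ancient Whole-Genome Duplications and
    Models of Chromosome-Number and Genome-Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative-genomics toolkit for detecting paleopolyploidy
    from collections of multilabeled gene trees and for modelling karyotype
    and genome-size evolution on a species phylogeny. Implements single-copy
    orthogroup reduction (collapsing well-supported single-species clades to
    their longest transcript), gene-tree-to-species-tree placement of
    duplication events from same-species paralog pairs with a
    taxon-composition plus sister-clade acceptance rule and a bootstrap
    filter, a continuous-time Markov chain model of chromosome-number change
    (dysploidy, polyploidy, demipolyploidy; constant or state-linear rates)
    with maximum-likelihood fitting, AIC/Akaike-weight model comparison,
    marginal ancestral states and stochastic-mapping event counts, and
    continuous-trait phylogenetic analyses (Brownian-motion ancestral
    reconstruction with confidence intervals, Pagel's lambda, Blomberg's K,
    phylogenetically independent contrasts, and Ornstein-Uhlenbeck shift
    selection by BIC). Includes simulators for species trees, duplication-
    loss gene families with an episodic whole-genome duplication, chromosome
    counts under an arbitrary rate matrix, and BM/OU traits, so the whole
    pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
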