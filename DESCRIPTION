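Package: oaktraits
Title: Wood Anatomical Trait Variation, Plasticity and Phylogenetic Signal
    Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analyses of wood anatomical traits in tree
    assemblages sampled along environmental gradients. Derives hydraulic
    variables from vessel and fibre measurements (vulnerability index,
    relative hydraulic conductivity, vessel composition index and lumen
    fraction), classifies leaf habit from annual canopy-foliage series,
    screens environmental variables by variance inflation, computes the
    relative distance plasticity index (RDPI) with plot-pair distance
    matrices and multiple regression on distance matrices (MRM) with
    permutation inference, classifies pairwise species co-occurrence under
    the exact hypergeometric model, and provides phylogenetic comparative
    statistics: independent contrasts, contrast correlations and PCA,
    Blomberg's K with a randomization test, Brownian-motion phylogenetic
    generalized least squares with AIC model selection, and simulation-based
    phylogenetic ANOVA with Holm-adjusted post hoc tests. A synthetic-data
    generator reproduces the sampling structure of a gradient study (species
    on a phylogeny, plots on an aridity gradient, niche-based occupancy,
    individual-level lognormal measurement noise) so every pipeline stage
    can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
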