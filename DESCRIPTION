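Package: ecoassembly
Title: Neutral and Null-Model Inference of Microbial Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the balance of stochastic and deterministic processes
    shaping microbial communities from an OTU table, a rooted phylogeny and
    sample metadata. Implements the Sloan neutral community model fit
    (immigration parameter m, R-squared, 95 percent prediction band),
    phylogenetic turnover null models (betaMNTD, betaNTI with tip-shuffling
    nulls), abundance-based Raup-Crick (RC-Bray), the five-way assembly
    process classification, the normalized stochasticity ratio (NST) with a
    permutational ANOVA group test, Blomberg's K phylogenetic signal of taxon
    niche values, Mantel and PERMANOVA driver tests, and thresholded Spearman
    co-occurrence networks with node topology metrics. A synthetic-community
    generator (Moran neutral drift and Gaussian environmental filtering on a
    Brownian-motion niche trait over a simulated phylogeny) provides ground
    truth for calibration of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
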