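Package: lambdascape
Title: Epistasis Decomposition and Evolutionary Trajectory Analysis on
    Mutational Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting epistatic adaptive evolution on a complete
    mutational hypercube. Decomposes a genotype-phenotype table over L
    biallelic sites into main and higher-order interaction effects by
    forward substitution on the subset-incidence system (equivalently,
    Moebius inversion on the subset lattice), with principled imputation of
    nonfunctional genotypes and closed-form standard errors. Enumerates all
    L! mutational orderings, classifies them by accessibility and per-step
    phenotype shifts, and infers the order of substitutions on a fixed
    rooted phylogeny by Fitch parsimony. Includes a seeded synthetic
    landscape generator, in-package fixtures, and file parsers for the
    landscape, tree and character-matrix formats. Motivated by the spectral
    tuning (lambda-max) evolution of vertebrate short-wavelength-sensitive
    visual pigments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
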