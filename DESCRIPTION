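Package: nicheshifts
Title: Niche-Shift Counting and Age-Corrected Sister-Pair Analysis of
    Ecological Speciation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating how often speciation coincides with an
    ecological niche shift in host-associated insect radiations. Codes
    species niches (larval feeding habit x host-plant set) as multistate
    characters with bespoke generalist step matrices, counts minimum
    niche shifts on phylogenies and Bayesian posterior tree samples by
    Sankoff parsimony, extracts terminal sister-species pairs with
    relative split ages, and fits a logistic regression of pairwise
    niche difference on split age whose extrapolation to age zero
    estimates the fraction of ecological speciation. Includes a
    birth-death simulator with cladogenetic and anagenetic niche shifts
    for validating the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
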