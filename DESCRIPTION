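Package: coalbias
Title: How Selection, Gene Conversion and Sampling Bias Distort Coalescent
    Demographic Inference in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of constant-size haploid
    (bacterial) populations with finite-sites JC69 mutation, point-mass
    selection and gene conversion, together with the downstream analyses
    whose neutral-model assumptions those forces violate: unfolded site
    frequency spectra and Tajima's D, ancestral-state misorientation
    correction, k-medoids (PAM) modelling of biased strain sampling, and
    classic/generalized (AIC-selected) skyline plots on UPGMA genealogies.
    Designed to show how selection, recombination and non-random sampling
    mimic demographic change in populations of constant size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
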