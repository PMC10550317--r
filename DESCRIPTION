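Package: infdom
Title: The Infinitesimal Model with Dominance on Explicit Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact two-, three-, and four-way identity-by-descent
    coefficients (Jacquard condensed identity states) on discrete-generation
    diploid pedigrees, a finite-locus Mendelian gene-dropping simulator for
    quantitative traits with additive and dominance effects, and the
    closed-form infinitesimal-model predictions for the shared and residual
    components of trait values within families, both unconditionally and
    conditional on parental trait values.  Includes a base-population
    generator for bi-allelic complete-dominance architectures with
    near-neutral allele frequencies, variance-component calculators
    (additive and dominance variance, inbreeding depression and its
    relatives), within-family truncation selection, genic versus total
    variance decompositions, and exact single- and two-locus posterior
    calculations for a toy bi-allelic trait.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
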