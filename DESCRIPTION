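Package: carriermod
Title: Genetic Modifier Discovery in High-Risk Mutation Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of penetrance modifiers in
    carriers of high-risk cancer-predisposition mutations ascertained through
    clinical genetics services. Implements the retrospective likelihood of
    genotypes conditional on disease phenotypes (censoring-age and affection
    status), a one-degree-of-freedom score test with kinship-adjusted variance
    for related carriers, hazard-ratio estimation with robust family-clustered
    standard errors, a configurable genotype/sample quality-control cascade with
    exact ledger accounting, MAGENTA-style gene-set enrichment of scan p-values,
    identity-by-descent segment sharing, PLINK file input/output, and a synthetic
    carrier-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
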