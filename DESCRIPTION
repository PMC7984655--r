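Package: mspenetrance
Title: Penetrance Bounds and Gene-Environment Response Curves for
    Multiple Sclerosis Susceptibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the lifetime probability of multiple sclerosis from
    measured prevalence, adjusts monozygotic-twin concordance for the shared
    intrauterine and early post-natal environment, bounds the size and sex
    composition of the genetically susceptible subset of the population via a
    size-biased penetrance identity, reconstructs sex-specific environmental
    exposure-response curves from the temporal change in the F:M sex ratio,
    and reconciles the curve plateaus with observed twin concordance by
    constraint-satisfaction grid search.  Includes a forward simulator of
    populations and twin and sibling families with latent heterogeneous
    penetrance, so every estimator is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
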