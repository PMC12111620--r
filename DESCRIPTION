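Package: epsimech
Title: Epsilon-Machine and Epsilon-Transducer Inference for Binary Behavior Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers minimal maximally predictive hidden-state models
    (epsilon-machines and input-output epsilon-transducers) from binary
    behavior time series with the Causal State Splitting Reconstruction
    (CSSR) algorithm, computes information-theoretic summaries
    (statistical complexity, excess entropy, entropy rate), averages
    hidden-state models across individuals via optimal state assignment,
    and runs population-level comparisons of self-driven versus
    socially-induced behavioral dynamics on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
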