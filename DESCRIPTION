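Package: motifblend
Title: Blended Generative-Discriminative Training of PWM Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains two-class position weight matrix (PWM) classifiers for
    transcription factor binding site recognition under a single objective
    that interpolates between conditional likelihood, joint likelihood, and
    a Dirichlet-type prior via a weight vector on the probability simplex.
    Maximum likelihood, maximum a posteriori, maximum conditional
    likelihood, maximum supervised posterior, and the penalized and
    unpenalized generative-discriminative trade-offs arise as special
    cases of the weight vector. Includes closed-form estimation for the
    generative edge of the simplex, quasi-Newton training elsewhere,
    stratified hold-out evaluation with sensitivity at fixed specificity,
    a simplex grid scan, and a synthetic benchmark generator emulating
    binding-site and genomic-background data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
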