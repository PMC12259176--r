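Package: memdecode
Title: Memorability-Corrected Decoding of Familiarity from Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how repetition
    suppression and image memorability jointly modulate the vigor of visual
    neural population responses, and how linear decoders that attenuate
    memorability recover familiarity behavior. Provides a seeded generator for
    two-presentation (novel/repeated) image sequences and Poisson spike counts
    from heterogeneous visually tuned units; unit and session screening filters
    and pseudopopulation assembly; grand-mean-firing-rate statistics with
    permutation tests for regression-slope differences; diagonal-covariance
    Fisher linear discriminant and population-vigor (all-ones) memory decoders
    with cross-validation, sliding-window time courses and ranked unit-removal
    curves; Poisson maximum-likelihood exponential tuning-curve fits with
    threshold-modification sweeps; and the rotated decoder family spanning the
    plane of the repetition-suppression and memorability axes, with a
    prediction-quality statistic that scores alignment between decoded and
    behavioral accuracy as a function of memorability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
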