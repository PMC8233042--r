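Package: okrsphere
Title: Optokinetic Response Tuning Across the Visual Field of Larval Zebrafish
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optokinetic response (OKR) experiments in a
    spherical LED stimulus arena. Provides fish-centred spherical geometry and
    arena-coverage calculations, repulsion-based placement of near-equidistant
    stimulus centres under mirror-symmetry constraints, saccade detection and
    piecewise-sinusoid fitting of eye-position traces to estimate OKR gain,
    bimodal von Mises-Fisher fitting and kernel smoothing of gain maps on the
    sphere, spatial-frequency and size tuning-curve fits, yoking and left/right
    bias indices with a two-stage asymmetry regression, exact permutation tests
    of group labels, and a seeded synthetic-data generator that emulates the
    statistical structure of the experiment so every stage is testable without
    animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
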