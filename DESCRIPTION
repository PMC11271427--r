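Package: bionicgait
Title: EMG-Driven Impedance Control and Gait Biomechanics for a Neuroprosthetic Ankle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing continuous neural control of a
    powered ankle prosthesis. Implements the myoelectric processing chain
    (finite-impulse-response band-pass, cumulative histogram filter,
    root-mean-square envelope, bilinear activation dynamics), a two-muscle
    decoder mapping tibialis anterior and gastrocnemius activations to an
    equilibrium angle and impedance level, an impedance controller bounded by
    biological maximal ankle torque, a minimal ankle plant for closed-loop
    gait simulation, a type II muscle-spindle afferent estimator with the
    agonist-antagonist afferent statistic, per-cycle gait biomechanics
    (events, peak power, net work, torque-angle loops, kinematic symmetry),
    and cohort-level statistics (correlations with confidence intervals,
    composite principal-component scores, normality-gated group comparisons).
    A synthetic-data module generates electromyography, fascicle strain,
    kinematics and cohort tables with controllable archetypes so the whole
    pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
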