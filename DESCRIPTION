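Package: dialexplore
Title: Modelling Internal and External Exploration in a Multiple-Option Dial Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a sequential multiple-option decision-making task in
    which an agent can reduce the uncertainty of a revealed option (internal
    exploration), reveal a new option elsewhere (external exploration), or
    accept an option and collect its payoff net of exploration costs. Provides
    the trinomial value-based choice model (a 10-parameter multinomial logit
    with accept as the reference category), per-participant maximum-likelihood
    fitting, BIC-based model comparison with random-effects Bayesian model
    selection (exceedance probabilities), parameter-recovery simulations,
    group-level behavioural statistics, and an event-locked region-of-interest
    (ROI) beta time-course analysis with leave-one-subject-out peak estimation,
    FWHM peak windows, FDR correction and Bayesian t tests. A synthetic-study
    generator produces complete sessions (choices, onsets, reaction times) and
    ROI BOLD series with planted regional value codes so the entire pipeline
    can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
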