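Package: pilotbe
Title: Simulation and Alternative Decision Methods for Pilot Bioequivalence Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Monte-Carlo evaluation of decision rules for pilot
    bioavailability/bioequivalence (BA/BE) crossover studies. Simulates
    2x2x2 crossover trials from a one-compartment population
    pharmacokinetic model with log-normal inter-individual and
    inter-occasion variability, derives non-compartmental summaries
    (Cmax, tmax, AUC to the last sample), and applies four decision
    methods to ln(Cmax): average bioequivalence (crossover ANOVA, 90%
    confidence interval, two one-sided t-tests), centrality of the
    geometric mean ratio, a sequence-balanced subject bootstrap with
    percentile confidence bounds, and the f2 similarity factor computed
    on Cmax-normalized mean concentration-time profiles. Includes exact
    power and sample-size calculations for the two one-sided tests
    procedure via Owen's Q function, and confusion-matrix performance
    summaries (sensitivity, specificity, precision, NPV, accuracy, F1,
    Matthews correlation, Cohen's kappa) over simulated truly
    bioequivalent and truly bioinequivalent trial sets.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
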