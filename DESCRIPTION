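Package: kineticSK
Title: Nonequilibrium Thermodynamics of the Asymmetric Kinetic
    Sherrington-Kirkpatrick Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying irreversibility in large disordered spin
    networks. Implements the kinetic Ising (Glauber) chain with quenched
    asymmetric Gaussian couplings -- the asymmetric Sherrington-Kirkpatrick
    model -- under synchronous and asynchronous updates; exact
    thermodynamic-limit mean-field theory for the order parameters,
    entropy rate, time-reversed conditional entropy, steady-state entropy
    production and order-disorder critical lines; Monte Carlo trajectory
    sampling with estimators of the same quantities; a brute-force
    enumeration oracle for small systems (stationary distribution,
    probability fluxes, detailed-balance diagnostics); and recurrence
    statistics of activity patterns. Results are returned as tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
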