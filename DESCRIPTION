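Package: replikin
Title: Stochastic Kinetics of DNA Replication Origin Firing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Well-mixed stochastic simulation of eukaryotic DNA replication
    kinetics. Potential replication origins are localized along chromosomes
    and fired by a limiting pool of diffusing firing factors through a
    bimolecular reaction; forks propagate at constant speed, passivate
    origins they pass over, and release their factor upon termination. The
    package reproduces the bell-shaped temporal rate of origin firing per
    unreplicated length, I(t), together with closed-form predictions for
    the critical free-factor threshold and the scaling law Imax = v * rho0^2.
    Includes origin-map file I/O (OriDB-style tab-separated maps), ensemble
    observables with bootstrap errors, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
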