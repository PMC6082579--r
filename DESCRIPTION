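Package: fptrecruit
Title: First-Passage-Time Models of DNA Repair Protein Recruitment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the recruitment of the DNA double-strand-break repair
    proteins MRE11 and NBS1 from the cytoplasm to the nucleus as radial
    Brownian motion between a reflecting cell membrane and an absorbing
    nuclear surface. Provides the Laplace-space first-passage-time flux and
    its short-time (Levy) and long-time (exponential) asymptotics, numerical
    Laplace inversion for intermediate times, a lattice kinetic Monte Carlo
    simulator, ensemble recruitment curves averaged over ribosomal starting
    positions, and least-squares inference of the starting-radius
    distribution from recruitment curves, with a synthetic-data generator
    for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, yaml, stats, graphics, grDevices, utils, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, pracma, optparse, knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
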