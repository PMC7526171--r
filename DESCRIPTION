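Package: cdgpp
Title: Guanine-Nucleotide Second-Messenger Dynamics in Caulobacter crescentus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic model of the guanine-nucleotide second-messenger network
    of Caulobacter crescentus: cyclic di-GMP, (p)ppGpp, GTP and GMP pools
    coupled to the nitrogen phosphotransferase system (PTS-Ntr) through
    glutamine sensing and SpoT synthetase/hydrolase partitioning. Provides
    the stiff seven-variable ODE system with cell-cycle-periodic diguanylate
    cyclase and phosphodiesterase abundance forcing, closed-form steady-state
    solutions used as an integration oracle, constrained sinusoid fitting for
    enzyme abundance time courses, nutrient-shift simulation protocols, and
    reproduction of the model's steady-state tables and oscillation ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
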