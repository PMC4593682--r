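Package: rumourscotch
Title: Rumour Spreading with Active Stiflers on Finite Populations and
    Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic simulation and analytical tools for an
    ignorant-spreader-stifler rumour process in which stiflers are active
    and "scotch" the rumour: a spreader informs an ignorant at rate lambda
    and a stifler silences a spreader at rate alpha.  Provides the
    continuous-time Markov chain on the complete graph (Gillespie
    simulation), its deterministic mean-field limit and the time-changed
    density-dependent system with closed-form solution, law-of-large-numbers
    and central-limit-theorem final-size asymptotics (limiting ignorant
    fraction, absorption time, asymptotic variance and Gaussian covariance
    machinery), quenched mean-field node-level ODEs on arbitrary graphs for
    both the scotching and the Maki-Thompson dynamics, generators for
    complete, Erdos-Renyi, Barabasi-Albert, power-law configuration-model
    and random regular graphs, a discrete asynchronous Monte Carlo scheme on
    networks, and reproducible experiment drivers (goodness-of-fit checks,
    phase diagrams, simulation-versus-theory comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
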