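Package: sexratioAD
Title: Adaptive Dynamics of Primary Sex Ratio Evolution in Two-Sex Matrix
    Population Models
Version: 0.1.0
Authors@R:
    person("Avery", "Hollis", email = "avery.hollis@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of the primary sex ratio
    (proportion of offspring born male) in continuous-time, two-sex,
    stage-structured populations with harmonic-mean mating and a
    reproducing union (pair) stage.  The package builds nonlinear,
    frequency-dependent projection matrices, integrates frequency
    dynamics to the equilibrium stage distribution, and applies adaptive
    dynamics: invasion fitness, analytic selection gradients via
    eigenvalue perturbation, location of evolutionarily singular sex
    ratios, and classification of their evolutionary and convergence
    stability from analytic second derivatives of invasion fitness
    (vec/Kronecker matrix calculus).  Five offspring-cost interpretations
    (identical sexes, resource costs, mortality during or after parental
    investment, and parental mortality costs), a four-stage no-union
    contrast model, pairwise invasion plots, parameter sweeps, and
    reproductive-value identities at singular strategies are included,
    along with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
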