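Package: bayescell
Title: Cell Decision Making as Bayesian Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models cell decision making as Bayesian learning of a cell's
    internal-state distribution from noisy microenvironmental sensing.
    Provides grid-based probability densities with information-theoretic
    functionals (differential entropy, Kullback-Leibler divergence, mutual
    and Fisher information), discrete-time Bayesian update dynamics and
    their fluctuation-dissipation identity, Gibbs-ansatz steady states
    driven by microenvironmental conditional entropy, a linear cell-sensing
    model with monostable-bistable regimes, the least-microenvironmental-
    uncertainty (LEUP) variational distribution, and a slow-fast Langevin /
    Fokker-Planck engine connecting entropy-derived drifts to stationary
    internal-state distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
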