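Package: modlabel
Title: Stochastic Gain Modulation as a Task-Relevance Label in Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying targeted stochastic gain modulation in spiking
    neural populations. Simulates modulated-Poisson populations with shared
    low-dimensional multiplicative modulators, fits stimulus-response (SR)
    Poisson regression and modulated-SR latent dynamical models (Poisson linear
    dynamical systems estimated by EM with a Laplace E-step), selects latent
    dimensionality by cross-validated leave-one-neuron-out prediction, decodes
    binary stimuli with ideal-observer, modulator-guided, sign-only and
    regression baselines, computes d-prime informativeness with a permutation
    null and related task statistics, and trains a small hierarchical network
    whose readout is fine-tuned through learned modulator couplings and a
    correlation-based gain rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
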