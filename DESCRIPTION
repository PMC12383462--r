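Package: quantneuron
Title: Quantum-Inspired Emulation of Stochastic Neuron Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing quantum-inspired models of
    single-neuron dynamics. Implements the stochastic FitzHugh-Nagumo model
    with additive voltage noise (Euler-Maruyama trajectory ensembles), the
    associated one-dimensional Fokker-Planck equation (conservative
    Chang-Cooper finite-volume scheme with reflecting boundaries), and the
    Nelson/Madelung reformulation of the voltage density as a
    Schrodinger-type equation with an effective potential and an effective
    "neuronal Planck constant", solved by a norm-preserving split-operator
    method in a cosine (Neumann) spectral basis. Also provides a dense
    statevector simulator for small qubit circuits (Trotterized neuron
    circuits, entangling two-neuron couplings, product-structure and
    entanglement diagnostics), estimators of the effective Planck constant
    from membrane-voltage recordings with a synthetic Ornstein-Uhlenbeck
    recording generator, density-comparison metrics (L1, Kullback-Leibler,
    Wasserstein-1), and an end-to-end stochastic-versus-quantum density
    equivalence experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
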