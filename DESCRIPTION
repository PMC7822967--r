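Package: synstd
Title: Short-Term Depression Dynamics and Quantal Analysis at GABAergic Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing short-term depression (STD) at
    GABAergic synapses from trains of inhibitory postsynaptic currents
    (IPSCs). Implements a calcium-driven vesicle depletion/recovery
    dynamical synapse model with calcium-dependent recovery, variance-mean
    quantal analysis (quantal amplitude, number of functional release
    sites, maximum release probability), train metrics (paired-pulse
    ratio, steady-state depression, coefficient of variation,
    readily-releasable pool size), IPSC waveform synthesis and kinetics,
    and Bayesian parameter estimation (MAP optimization followed by
    adaptive-Metropolis MCMC). A stochastic binomial quantal simulator
    generates experiment-shaped synthetic datasets so the whole pipeline
    is testable without recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
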