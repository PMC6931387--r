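Package: affectinf
Title: Active Inference Simulation of Emotional State Inference and Emotion Concept Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-state (POMDP) active inference agent that infers its
    own emotional state by sequentially directing attention to interoceptive,
    proprioceptive, and exteroceptive cues, and that acquires emotion concepts
    by Dirichlet learning of its likelihood mapping from social feedback.
    Provides the generative model constructors (likelihoods, controllable
    attention transitions, preferences, habit priors), a variational inference
    and expected-free-energy engine with simulated neural readouts, between-
    trial concentration-parameter learning, a generative-process sampler with
    configurable precision, and the full set of developmental simulation
    protocols: precision sweeps, childhood and adulthood concept acquisition,
    skewed early experience, and maladaptive attention-bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, grDevices, graphics
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.2
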