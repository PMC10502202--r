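Package: hbsl
Title: Hierarchical Bayesian Statistical Learning of Auditory Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates statistical learning of melodic sequences with a
    Dirichlet-prior Markov model that tracks, for every transition, not only
    its probability but the reliability (inverse variance) of that
    probability. Sensitivity regimes scale the Dirichlet concentrations to
    mimic hypo-, normal- and hyper-sensitive learners; Bayesian surprise
    (Kullback-Leibler divergence of the predictive distribution across each
    observation) traces the learning dynamics; jointly probable and reliable
    transitions are chunked and re-encoded as units of a second-level model;
    and learned models compose new melodies whose statistics and rhythm are
    compared with the training piece via bigram Jensen-Shannon divergence
    and a probabilistic amplitude demodulation (PAD) cascade yielding
    amplitude-modulation band powers. Includes Standard MIDI File and WAV
    input/output and a synthetic children's-song fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
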