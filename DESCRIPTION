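Package: neuralmp
Title: Neuronal Message Passing for Discrete Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Belief propagation, variational (mean-field) message passing,
    and marginal message passing for discrete hidden Markov models,
    implemented both as scheduled fixed-point algorithms and as
    continuous-time gradient descents with neuronal semantics (membrane
    potentials, softmax firing rates, prediction-error units).  Includes
    the variational, Bethe, and marginal free-energy functionals, an exact
    enumeration oracle, seeded model and sequence generators, and an
    online evidence-accumulation harness for comparing the schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
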