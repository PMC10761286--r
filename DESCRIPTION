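Package: bubblesim
Title: Coupled Disease and Knowledge Spreading on Temporal Social-Bubble Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based co-simulation of a non-Markovian SIR epidemic (with
    symptom-driven isolation, seven-day contact tracing and preventive
    quarantine) and a multi-strain threshold-with-memory knowledge contagion,
    both unfolding on synthetic modular temporal contact networks generated by
    a stochastic block model under a fixed expected-link budget. Supports
    "temporal social bubbles": round-robin pairing of communities that
    concentrates all inter-community contacts between matched pairs for
    fixed-length rounds. Provides scenario ensembles, intervention sweeps
    (quarantine probability, modularity, pairing period) and the associated
    indicators: peak simultaneous infections, knowledge milestone times,
    collateral confinement and realized modularity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
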