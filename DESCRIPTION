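Package: taskstates
Title: Latent-State Generalization Task Simulation, Spreading-Activation
    Reaction-Time Models, and Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how abstract latent task states support
    generalization of learned values to novel conditions. Provides a
    generator for a three-phase context-category betting task in which
    nine contexts cluster into three latent states by their shared
    category-value associations; four spreading-activation memory-network
    models (conjunctive and independent associative retrieval, latent
    state, and hierarchical latent state) that map generalization trial
    sequences to predicted reaction times via Rescorla-Wagner activation
    dynamics; maximum-likelihood model fitting with multi-restart bounded
    optimization, cross-model and parameter recovery; behavioral
    learning-curve, switch-cost, and latent-state repetition analyses;
    and a representational similarity analysis pipeline with hypothesis
    dissimilarity matrices, cross-validated Mahalanobis (crossnobis)
    distances, multiple regression, and group-level tests. Synthetic
    behavioral cohorts and multivoxel pattern datasets make every stage
    runnable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
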