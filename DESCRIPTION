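Package: stdpmem
Title: Associative Memory via Spike-Timing-Dependent Plasticity and
    Tensor-Product Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stores groups of tensor-product-encoded data vectors in an
    antisymmetric synaptic connectivity matrix through delayed
    spike-timing-dependent plasticity dynamics, and retrieves them as
    neural oscillations near a two-dimensional memory plane when cued.
    Provides a second-order predictor-corrector integrator for the coupled
    state/plasticity delay system, an analytic phasor oracle for the linear
    retrieval system, memory-plane geometry and retrieval-quality metrics,
    grouped-image and semantic-sentence experiment drivers with synthetic
    image fixtures, a memory-capacity sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
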