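Package: confmap
Title: Mapping Macromolecular Conformations from Heterogeneous Snapshot Datasets by Manifold Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sorting discrete conformations and mapping conformational
    continua of macromolecules from large sets of noisy two-dimensional
    snapshots (cryo-EM images or single-particle diffraction patterns).
    Implements a defocus-invariant "double-filtered" snapshot distance, an
    orientation-gated Gaussian kernel for diffusion maps, diffusion-map and
    Isomap embeddings, and two-class spectral sorting with fidelity and
    manifold-separation statistics.  Includes a synthetic snapshot forge
    (Gaussian-blob phantoms, uniform or single-axis orientations, contrast
    transfer function, background plus shot noise, photon-sparse diffraction)
    so every stage can be exercised without external data, plus MRC stack and
    CSV-sidecar input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
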