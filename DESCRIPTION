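Package: elbench
Title: Benchmarking Toolkit for Cryo-EM Conformational Heterogeneity Methods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates single-particle cryo-EM image stacks from a known
    two-coordinate conformational energy landscape acting on a two-body
    ribosome-like phantom (fixed large subunit, small subunit rotating about
    two orthogonal axes), and scores any recovered low-dimensional
    conformational embedding against that ground truth: per-well recall,
    balanced accuracy, occupancy maps, Boltzmann-inverted energy landscapes
    and data-lineage coloring. Includes reference embeddings and controlled
    distortions so the evaluation pipeline runs end-to-end without external
    heterogeneity software, plus MRC/MRCS and Relion-dialect STAR readers
    and writers for interoperability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
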