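Package: eisparse
Title: Volume-Constrained Sparse Coding and the Cortical E:I Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the ratio of excitatory to inhibitory
    neurons in recurrent sparse-coding circuits under a fixed total
    neuron budget. Learns overcomplete dictionaries for natural image
    patches, factorizes the required recurrent connectivity through a
    rank-limited inhibitory interneuron population via truncated SVD,
    encodes stimuli with locally competitive algorithm (LCA) dynamics,
    and scores circuits by reconstruction error, Treves-Rolls population
    sparsity and a metabolic energy budget across E:I ratios and
    sparsity levels. Also provides Treves-Rolls sparsity estimation for
    binned spike data with hierarchical-bootstrap group comparisons, and
    seeded synthetic generators (1/f images, planted-dictionary patches,
    nested spike counts) for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), png, tiff, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
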