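Package: plasmidyn
Title: Dynamics, Replication and Partition of High-Copy Bacterial Plasmids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the intracellular dynamics of high-copy
    ColE1-type plasmids. Provides mean-square-displacement (MSD) computation
    and confined-diffusion (Kusumi-form) fitting for single-particle tracks,
    relative copy-number quantification from qPCR with a cell-cycle
    copy-number model, Poisson statistics of stochastic replication events
    (EdU labelling and replisome-marker lifetimes), a stochastic whole-cell
    simulator of nucleoid-excluded hop diffusion with constant-probability
    replication and random positional partition, and seeded synthetic-data
    generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
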