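Package: telodyn
Title: Single-Particle Tracking and Diffusion Analysis for CRISPR-Labeled Genomic Loci
Version: 0.1.0
Authors@R: person("telodyn", "maintainers", email = "telodyn@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of live-imaging movies of fluorescently
    labeled genomic loci (e.g. telomeres tagged with dCas9-EGFP): Laplacian-of-
    Gaussian spot detection in 2D frames and 3D stacks, nearest-neighbor
    trajectory linking with gap closing, trajectory and cell filters, nucleus
    drift correction, time-averaged mean-squared-displacement estimation,
    least-squares fitting of anomalous (MSD = 4*D_a*t^a) and confined-plus-
    macroscopic (MSD = A*(1-exp(-t/tau)) + 4*D_macro*t) diffusion models, 3D
    foci aggregation and two-channel colocalization quantification, and a
    synthetic-data generator (exact fractional Brownian motion, Ornstein-
    Uhlenbeck confined motion, noisy movie rendering) so the full pipeline is
    testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
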