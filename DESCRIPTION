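Package: motileCTRW
Title: Single-Cell Tracking and Continuous-Time Random Walk Models of
    Bacterial Ensemble Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying run-and-tumble motility of individual
    bacteria from bright-field video microscopy and for predicting their
    ensemble transport. Provides a synthetic-data generator for
    run-and-tumble trajectories with heavy-tailed jump-length and
    waiting-time distributions rendered as microscopy-like frame stacks;
    intensity-based cell detection and nearest-neighbour trajectory
    linking; segmentation of trajectories into jumps and waiting periods;
    empirical jump/wait distributions, ensemble moments, drift speed and
    lag-1 step correlations; Monte-Carlo continuous-time random walk
    (CTRW) simulation in coupled and uncoupled variants; an
    advection-diffusion breakthrough model with time-varying diffusion
    coefficient; and first-passage (breakthrough) curve comparison at
    radial control planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    graphics,
    pracma,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
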