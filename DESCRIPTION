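Package: seqviolate
Title: Motion-Sequence Learning Stimuli, Reproduction Scoring, and
    Spatiotemporal Cluster Statistics for ERP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sequence-learning experiments in which observers
    watch and reproduce short multi-segment motion trajectories while
    scalp EEG is recorded.  Generates constrained five-segment motion
    stimuli and their 180-degree "flip" deviants, builds block-randomized
    session schedules, segments stylus reproductions and scores them by
    directional error, converts epoched multichannel EEG into condition
    event-related potentials (average reference, zero-phase bandpass,
    artifact-threshold rejection, subject and grand averaging), runs
    adjacency-constrained spatiotemporal cluster-based permutation tests
    with a max-statistic null, and compares amplitude-normalized
    topographies with repeated-measures ANOVA (Greenhouse-Geisser
    corrected).  A synthetic-data module emulates the behavioral and
    electrophysiological structure the analysis assumes, so the full
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
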