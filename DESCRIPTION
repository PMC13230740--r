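Package: roundfish
Title: Simulation, Orchestration and Round-Wise Analysis of Sequential
    smFISH Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated sequential single-molecule FISH
    (smFISH) experiments: a synthetic multi-round image generator with
    known ground truth, Laplacian-of-Gaussian spot detection with
    per-spot intensity/background/SNR metrics, phase cross-correlation
    drift registration, Hungarian-algorithm cross-round spot
    colocalization, Helmli-Scherer mean-ratio focus scoring with
    best-plane composites, gene-by-cell expression matrices with
    cosine-distance cell-type calling, and a fully simulated fluidics
    rig (valve, peristaltic pump, flow sensor, plate robot) driven by a
    declarative run specification with acquisition-trigger handshakes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
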