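Package: striatlearn
Title: Operant Bout Microstructure, Miniscope Calcium Events, and Whole-Brain c-Fos Density Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of instrumental-learning
    consolidation in the dorsal striatum. Implements inter-response-interval
    epoch probabilities and the 5-second response-bout partition of operant
    event logs (bout frequency, bout density, solitary presses); a miniscope
    calcium processing chain (homomorphic illumination correction, rigid
    motion correction, background subtraction, circular-ROI trace extraction,
    whole-trace delta-F-over-F, 3-SD event detection, events per minute); a
    simplified whole-brain c-Fos cell-detection recipe (morphological-opening
    background removal, difference-of-Gaussians enhancement, peak threshold,
    seeded watershed, size gate) with atlas-free binning of cell coordinates
    into striatal subregions, volume-normalized densities, Z-scoring,
    mutual-KNN covariance clustering and a 2-D stochastic-neighbor embedding;
    routine group statistics; and a synthetic-data module that generates every
    input with known ground truth (reinforcement-schedule simulation, bouted
    press streams, calcium traces and movies, 3-D cell clouds).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
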