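Package: connsweep
Title: Condition-Weighted Connectome Graph Analysis with Cost-Sweep Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretical analysis of task fMRI functional connectomes:
    hemodynamically weighted per-condition correlation networks over a
    160-node functional atlas, proportional-threshold cost sweeps with
    binary graph measures (degree centrality, clustering coefficient,
    eccentricity), degree-preserving random and lattice rewiring null
    models with small-world regime detection, area-under-curve
    summarization into six functional networks, condition deltas and
    connectivity decomposition, and mixed-design (M)ANCOVA group
    statistics with Mauchly/Greenhouse-Geisser sphericity handling and
    Tukey-adjusted post hoc contrasts. Includes framewise-displacement
    motion quality control, aCompCor-style denoising, and a synthetic
    cohort generator with known ground-truth connectivity structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    car,
    withr
Config/testthat/edition: 3
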