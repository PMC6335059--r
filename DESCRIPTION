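Package: secasym
Title: Asymmetry Analysis of Pre-Protein Translocation Through the SecY Channel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for quantifying ATP-driven asymmetry
    across the SecY protein-conducting channel. Provides hydrogen-bond based
    secondary-structure assignment (Kabsch-Sander subset) and per-cavity
    folding-degree statistics, sphere-probe pore-radius profiling with
    trapezoidal cavity-volume integration, prism-sliced water mean-squared
    displacement analysis with power-law exponent fitting, elastic-network
    deformation energies, spin-label distance distributions (modal distance
    and full width at half height), steered-passage time extraction, and
    differential hydrogen-deuterium exchange classification. A synthetic-data
    module generates every input class with known ground truth (fractional
    Brownian water baths, ideal helical backbones, analytic channel-shaped
    atom clouds, spin-label ensembles, replicate HDX uptake tables) so that
    every stage is verifiable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
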