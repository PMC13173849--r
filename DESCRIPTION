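Package: bfhc
Title: Bay, Fjord, Harbor and Canyon Topological Indices for Polycyclic
    Aromatic Hydrocarbons
Version: 0.1.0
Authors@R:
    person("BFHC", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Perceives molecular graphs of carbon/hydrogen-only polycyclic
    aromatic hydrocarbons (PAHs) from raw Cartesian coordinates (plain XYZ
    or Gaussian-input dialects), identifies rings by a minimum cycle basis,
    walks the perimeter of the fused-ring system, and detects concave
    boundary regions -- Bay (4-atom path), Fjord (5), Harbor (6) and Canyon
    (7) -- together with a linear / angular (cata-condensed) /
    peri-condensed classification of the fused benzene-ring topology.
    Includes an idealized benzenoid geometry builder (hexagonal lattice,
    helicene spirals) with ground-truth connectivity for testing, an
    independent brute-force motif oracle, and tools to read, validate and
    summarize QSAR-ready PAH metadata tables carrying BFHC counts, a
    seven-level ordinal carcinogenicity scheme, log P and log Iball.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
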