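Package: porenet
Title: Hydrogen-Bond Network Analysis of Membrane Peptide Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze the dynamic hydrogen-bond networks that
    stabilize peptide nanopores in lipid bilayers. Detects hydrogen bonds
    from molecular dynamics trajectories using geometric criteria, searches
    for water-mediated bridges of up to three waters, aggregates per-frame
    bridges into occupancy-filtered residue interaction graphs with peptide
    side-chain and lipid-phosphate nodes, and derives per-residue
    interaction densities and pore descriptors (bridge-count time series,
    phosphate and tryptophan insertion depths, transmembrane water
    connectivity). Includes sequence-level descriptors (net charge, helical
    wheel, sliding-window hydropathy), dose-response arithmetic for vesicle
    leakage and lipid-exchange assays with mole-fraction partition
    coefficient fitting, and a synthetic pore-trajectory generator with
    fully known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
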