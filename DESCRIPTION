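Package: pixkit
Title: Crystal Packing Analysis with Pixel-Style Energy Partitioning Support
Version: 0.1.0
Authors@R: person("Pix", "Kit", email = "pixkit@example.org", role = c("aut", "cre"))
Description: Tools for analysing intermolecular interactions in molecular
    crystals. Parses CIF files (CSD and SHELXL dialects), completes molecules
    across space-group symmetry including special positions, normalizes
    hydrogen positions to neutron-derived bond lengths, enumerates
    symmetry-related molecular pairs within a centroid cutoff with ORTEP-type
    symmetry codes, performs an indicative structure analysis (hydrogen-bond
    detection with exponential energy estimates, van der Waals contact
    fractions, one-dimensional packing motif detection, driver lists and
    half-sum lattice-energy estimates), condenses Gaussian-format
    electron-density cubes into charge pixels with a pixel-sum Coulomb
    energy, and annotates whitespace-format interaction-energy tables for
    spreadsheet use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
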