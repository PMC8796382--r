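Package: molcloud
Title: Multi-Conformation Point-Cloud Toolkit for Biomolecular Structures
Version: 0.1.0
Authors@R: person("molcloud", "developers", role = c("aut", "cre"),
    email = "molcloud@example.org")
Description: Represents biomolecular structures as multi-conformation point
    clouds with per-point metadata, and provides the operations a typical
    integrative-modelling workflow needs: multi-model PDB and OpenDX
    input/output, interconversion between point clouds and simulated
    electron-density maps with mass-based isovalue selection, symmetric
    assembly on deformable polyhedral scaffolds and cyclic axes,
    super-coarse-grained sphere and ellipsoid models, collision cross
    sections by the rotationally averaged projection approximation,
    Shrake-Rupley solvent-accessible surface areas, and solvent-accessible
    shortest paths on a lattice graph for cross-link feasibility checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
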