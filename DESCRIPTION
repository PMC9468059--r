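Package: lctau
Title: 3D Quantification of Cellular Tau Pathology in the Locus Coeruleus
Version: 0.1.0
Authors@R:
    person("LC", "Imaging Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hyperphosphorylated-tau (AT8) pathology of
    noradrenergic (TH+) neurons in volumetric light-sheet scans of the human
    locus coeruleus / pericoerulear complex. Provides a synthetic phantom
    generator emulating the statistical structure of cleared-tissue two-channel
    volumes, 3D soma detection with watershed splitting, decomposition of the
    AT8 signal into cell-body and process compartments, concentric-shell
    process zoning, equal-volume dorso-ventral splitting, Monte-Carlo
    nearest-neighbour-index and duo/minigroup cluster statistics, regional
    burden quantification with semiquantitative scoring, and a thin
    statistical-reporting layer. All geometry is computed in physical
    micrometres on anisotropic voxel grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
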