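Package: memion
Title: Membrane-Surfactant Trajectory Analysis and Boundary-Potential Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of hydrophobic-ion behaviour in lipid bilayers from
    molecular-dynamics style trajectories, together with the electrostatic
    measurement model for planar-bilayer boundary-potential experiments.
    Reads GRO and multi-MODEL PDB trajectories with a role map identifying
    anchor atoms and partial charges; computes surfactant orientation-angle
    (eta/theta) distributions, species-resolved charge-density profiles
    along the membrane normal with peak extraction, cholesterol cluster-size
    distributions under periodic boundaries and midplane plunge (flip-flop)
    events; models boundary potentials via Gouy-Chapman/Grahame theory with
    self-consistent Langmuir adsorption of charged surfactants, fits
    inner-field-compensation capacitance scans, and converts nonactin
    conductance ratios to potential changes. A synthetic-system generator
    with known ground truth makes every analysis stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
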