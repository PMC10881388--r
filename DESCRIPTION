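Package: trsfx
Title: Desk-Scale Analysis Pipeline for Time-Resolved Serial Femtosecond
    Crystallography of Ligand Photolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for pump-probe time-resolved
    serial femtosecond crystallography (TR-SFX) studies of ligand photolysis
    in heme proteins. Generates a synthetic two-state (CO-bound versus
    photodissociated) protein-heme crystal system with scheduled femtosecond
    structural dynamics; computes structure factors by direct summation,
    isomorphous difference and omit maps, and light-to-dark Wilson scaling;
    estimates photoproduct occupancy from difference-density peak ratios,
    multicopy titration with zero-crossing, and structure-factor
    extrapolation; measures heme out-of-plane iron displacement, doming,
    difference-distance matrices, displacement-from-heme profiles and radius
    of gyration; provides timing-tool style delay binning, Monte-Carlo
    merging of partial serial intensities, exponential-rise and
    damped-cosine kinetics fits, and frame-level bootstrap uncertainties;
    and implements Beer-Lambert/Poisson photoexcitation-regime arithmetic
    (absorbed photons per chromophore, peak power density, penetration
    depth, depth-resolved multiphoton fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
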