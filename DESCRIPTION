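Package: ventriflow
Title: Immersed-Boundary Simulation of Left-Ventricular Flow and Mitral
    Regurgitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates intraventricular blood flow in a moving left-ventricle
    cavity with a flow-driven two-leaflet mitral valve, using a sharp-interface
    immersed-boundary fractional-step solver for the incompressible
    Navier-Stokes equations on a staggered Cartesian grid. Includes a synthetic
    geometry generator (healthy and dilated ventricles, healthy and prolapsed
    valves with a controllable coaptation defect), passive-scalar blood-transit
    tracking, and a quantification suite for mitral regurgitation: effective
    orifice area, true and false regurgitant volumes, old-blood regurgitation
    and ventricular residual volume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
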