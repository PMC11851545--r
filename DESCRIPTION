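Package: aneuNO
Title: Idealized Aneurysm Hemodynamics and Nitric Oxide Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator for pulsatile blood flow and coupled
    nitric oxide (NO) transport in idealized abdominal aortic aneurysm
    geometries. Solves incompressible Newtonian flow on boundary-fitted
    structured grids via a stream-function-vorticity formulation, couples
    wall shear stress to shear-modulated endothelial NO production through
    a hyperbolic response law, and transports NO through the lumen
    (convection-diffusion with oxidation and red-blood-cell scavenging)
    and the arterial wall (diffusion with first-order consumption).
    Computes wall-based hemodynamic indices (TAWSS, OSI, RRT, ECAP, WSSG,
    TAcNO), and implements a cross-sectioning and least-squares correlation
    protocol linking intraluminal thrombus burden to NO concentration,
    together with a synthetic-study generator that makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
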