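Package: biofilmIB
Title: Immersed-Boundary Simulation of Viscoelastic Biofilm Growth in Shear Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A 2D hybrid fluid-structure simulator for biofilms attached to a
    microchannel wall. The biofilm is a triangulated Lagrangian network of
    viscoelastic Maxwell (or purely elastic Stokes) spring elements coupled to
    an incompressible Newtonian fluid through the Immersed Boundary Method with
    the Peskin four-point regularized delta kernel. Nutrient concentration
    follows an advection-diffusion-reaction equation with Monod uptake
    kinetics, and the biofilm grows by a stochastic rule that spawns new
    boundary triangles with probability proportional to the local specific
    growth rate. Includes a DistMesh-style semicircular mesh generator, a
    spectral (FFT) projection Navier-Stokes solver on a doubly periodic
    domain, a virtual creep-test rheometry harness, and post-processing of
    center-of-mass migration rates and biomass ratios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
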