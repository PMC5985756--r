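Package: cardioemf
Title: Electro-Mechano-Fluidic Simulation of the Left Ventricle and Aorta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for coupled cardiac electromechanics and
    hemodynamics on idealized anatomies. Generates labeled simplicial meshes of
    a truncated-ellipsoid left ventricle and a (optionally coarcted) aortic
    tube, computes anisotropic eikonal activation maps with a reaction-eikonal
    monodomain option, solves quasi-static hyperelastic mechanics (Guccione and
    Demiray materials with an active stress transient) coupled to three-element
    Windkessel afterload models, fits passive stiffness against the Klotz
    end-diastolic pressure-volume relation by backward-displacement unloading,
    transfers wall kinematics to a finer non-conformal fluid mesh through a
    pseudo-elastic mesh-motion solve with quality-based stiffening, and runs a
    stabilized (residual-based variational multiscale) equal-order finite
    element solver for incompressible Navier-Stokes flow on moving meshes,
    including backflow-stabilized Windkessel outlets and a pressure-Poisson
    mapping from velocity fields to relative pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
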