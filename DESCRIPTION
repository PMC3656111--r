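Package: memdef
Title: Bilayer Thickness Deformations and Gating of Non-Circular Membrane Inclusions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuum-elasticity model of the lipid bilayer thickness
    deformations induced by rigid membrane inclusions whose transmembrane
    cross section deviates from a circle (regular polygons, clover-leaf
    shapes, or arbitrary low-order Fourier boundaries). Solves the
    fourth-order thickness-deformation Euler-Lagrange equation on the
    exterior of the inclusion by a Fourier-Bessel series after mapping the
    non-circular boundary conditions, to leading order in the boundary
    perturbation, onto an equivalent cylinder of variable hydrophobic
    thickness. Provides closed-form deformation energies, a decomposition
    of the energy into cylinder and shape contributions, two-state
    Boltzmann gating curves and gating tensions for mechanosensitive
    channels such as MscL, independent finite-difference oracles for
    solver verification, and extraction of boundary shapes from protein
    structures in PDB format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
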