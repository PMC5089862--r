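Package: crowdbd
Title: Brownian Dynamics and Trajectory Analysis of Crowded Cytoplasm Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics of polydisperse sphere models of
    crowded cellular cytoplasm, with half-harmonic excluded-volume repulsion,
    Lennard-Jones and screened-Coulomb pair options, and optional far-field
    (Rotne-Prager-Yamakawa) hydrodynamic coupling. Provides a trajectory
    analysis toolbox: windowed mean-square displacements and translational
    diffusion fits with Stokes-radius scaling laws; rotational correlation
    functions, relaxation times and mean angular velocities of rigid bodies;
    crowder coordination numbers and quinary-interaction statistics across
    macromolecule groups; proximal radial distribution functions with
    voxel-based accessible volumes and three-dimensional density grids; and
    structural observables (core RMSD with fluctuation filtering, radii of
    gyration, ligand-site distances, contact pairs). Synthetic-data
    generators supply free Brownian walkers, rigid rotors, packed
    polydisperse configurations and bidisperse Lennard-Jones mixtures with
    known ground truth, so every estimator can be validated against analytic
    or brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, tools, jsonlite, yaml, minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), bio3d, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
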