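---
title: "Brownian dynamics and trajectory analysis of crowded cytoplasm models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian dynamics and trajectory analysis of crowded cytoplasm models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdbd)
```

## The model

A bacterial cytoplasm at 300-450 g/L of macromolecules (25-45 vol%) is, to
first order, a dense polydisperse suspension: ribosome-sized complexes
(Stokes radius around 100 A) down to small proteins (around 16 A) exclude
each other's volume, slow each other's diffusion, and bias small molecules
onto macromolecular surfaces.  `crowdbd` implements the coarse-grained
layer of that picture: every macromolecule is a sphere with radius equal to
its Stokes radius `Rs`, so that its dilute-limit translational diffusion is
Stokes-Einstein, `D0 = kBT / (6 pi eta Rs)`, and its excluded volume is the
sphere itself.

Spheres repel through a half-harmonic contact potential

    V(r) = k/2 (r - a_i - a_j - Delta)^2   for r <  a_i + a_j + Delta
    V(r) = 0                               for r >= a_i + a_j + Delta

with buffer `Delta = 1 A` and force constant `k = 10 kBT/Delta^2`, which
puts exactly 5 kBT at sphere-sphere contact (`pair_energy()`).  The
potential is zero at and beyond the cutoff and continuous with continuous
first derivative there; configurations have non-negative energy that
vanishes iff no pair is inside its buffer.  Lennard-Jones and
LJ-plus-Coulomb forms (contact distance `sigma_ij = a_i + a_j`, default
well depth 0.2 kBT, Bjerrum length 7.1 A for water at 298 K, minimum-image
truncation at L/2) serve the small-particle mixture experiments.

Units are fixed package-wide: Angstrom, picosecond, Kelvin, kBT for
energies, elementary charges, and A^2/ps for diffusion constants
(1 A^2/ps = 1e-4 cm^2/s).

## Propagation

`run_simulation()` integrates overdamped (Brownian) dynamics.  The default
scheme is the second-order predictor-corrector: a predictor step
`x* = x + D F(x) dt + xi`, then a corrector using the force averaged
between the endpoints, `x' = x + D (F(x) + F(x*))/2 dt + xi`, with the
*same* Gaussian noise realization `xi` (per-axis variance `2 D dt`) in
both half-updates.  The plain first-order update is available as
`ermak_mccammon`.  Both draw their noise from R's RNG, so a run is exactly
reproducible from its seed regardless of system size.

The timestep rule is `dt = 0.0005 a_min^2 / D(a_min)` for the smallest
radius in the system (`suggest_timestep()`); it is cubic in `a_min` and
gives the standard 8 ps step for `a_min = 15.8 A` in water at 298 K.  The
two-sphere equilibrium test in the suite shows why the rule matters: at
the rule-based step the sampled pair-distance distribution matches
Boltzmann quadrature to better than 1%, while at many times the rule the
1 A interaction buffer is crossed in single steps and the sampled
distribution deforms.  At twice the rule the second-order corrector shows
measurably smaller equilibrium bias than the first-order scheme; at very
large steps (several times the rule) neither scheme is trustworthy and the
corrector's force extrapolation can even overshoot more than the plain
update, which is one more reason the package treats the timestep rule as a
default rather than a suggestion.

Neighbor search is a linked-cell grid with one refinement for strongly
polydisperse systems: particles larger than 60% of the maximum radius
(at most one eighth of the system; ribosomes and GroEL in the cytoplasm
composition) are swept all-pairs, and the cell size is set by the largest
*remaining* pair cutoff.  Without the split, a single ribosome-sized
cutoff forces cells so coarse the grid degenerates to all-pairs.  The
cell path is bit-identical to the all-pairs path; that equality is a
tested invariant, not an approximation.

Far-field hydrodynamic coupling is available as the Rotne-Prager-Yamakawa
diffusion matrix (`rpy_mobility()`, symmetric positive-definite for
non-overlapping spheres, Stokes-Einstein self-blocks) with
Cholesky-correlated noise and a midpoint re-evaluation of the
configuration-dependent mobility; RPY is divergence-free so no spurious
drift correction is needed.  This dense-matrix path is meant for small
systems; near-field lubrication corrections are out of scope, so the
package's hydrodynamic results are far-field only.

## The synthetic cytoplasm and what it does (not) represent

Because per-species copy numbers of the organism's cytoplasm are not
bundled, `synthetic_cytoplasm()` provides a synthetic stand-in: nine
species from ribosome (105 A, net charge -50) to a small protein (15.8 A),
81 molecules at base scale, multiplied by the standard eightfold
copy-scaling rule for the production system (648 spheres; ribosome and
GroEL go 3 to 24).  The matching box (`synthetic_cytoplasm_box()`) is
sized for a sphere volume fraction of 0.45 -- the top of the physical
25-45 vol% range, appropriate because Stokes radii inflate molecular
volumes relative to physical (van der Waals) volumes.  The smallest radius
is 15.8 A so that the composition is self-consistent with the 8 ps
timestep rule.  These are the package's study conditions; they are fixed,
not tuned per analysis.

Real cytoplasm differs in ways this model deliberately omits: molecules
are not spheres, interactions include attraction, electrostatics and
hydration (the model's spheres are purely repulsive unless the LJ/Coulomb
forms are chosen), and hydrodynamic coupling is neglected in the default
BD mode.  Consequently passing tests demonstrate correct *estimators and
machinery* on systems with known ground truth -- they do not claim the
synthetic composition reproduces any particular organism's absolute
diffusion map.

`gen_packed_configuration()` builds initial states by largest-first random
sequential insertion; if insertion stalls, stragglers are placed randomly
and relaxed by soft-start BD (forces capped at 10 kBT/A, alternating noisy
and noiseless capped-gradient chunks) until no pair overlaps -- the
half-harmonic potential is zero beyond `a_i + a_j + Delta`, so capped
gradient descent terminates in an overlap-free state whenever the volume
fraction admits one (the generator refuses requests above 0.55).

## Diffusion analysis

`compute_msd()` implements windowed mean-square displacements: origins
advance in `dt_i` steps from the trajectory start to `tend - tau_max` (the
same origin set for every lag), displacements are averaged over origins,
selected particles, and optionally molecule centers of mass.  The
estimator equals a brute-force double loop exactly; that equality is a
test.  Trajectories must be unwrapped first (`unwrap_trajectory()`);
feeding wrapped coordinates is an error, not a warning, because box jumps
corrupt displacements silently.  Unwrapping flags any minimum-image step
at or beyond 40% of the box edge as ambiguous: a true displacement
approaching L/2 cannot be assigned reliably, and in that regime the frame
rate, not the unwrapping, is the problem.

`fit_dtr()` turns an MSD curve into `D_tr = slope/6` (or `slope/4` for
two-dimensional surface diffusion).  The default fits the last 80% of the
curve, which suppresses the short-lag region where windowed statistics are
most correlated and cage or ballistic contamination lives; the full-range
variant exists for crowding-correlation analyses.  Window length matters:
time-averaged MSD values at lags comparable to the trajectory length are
strongly correlated, so accurate recovery needs `tau_max` well below the
span (the tests use about 10%; with that choice the estimator recovers
known walker diffusivities within a few percent).

`fit_size_scaling()` fits the standard one-parameter laws through the
origin in the transformed variable -- `D = A/Rs^2`, `D/D0 = B/Rs` -- plus
a free-exponent power law for the radius-weight relation `Rs = c Mw^b`
(the exponent is estimated, never assumed) and an ordinary linear law for
normalized diffusion against normalized coordination number.

`classify_surface_diffusion()` labels a metabolite frame "interacting"
when it lies within a per-species cutoff (8-10 A) of the nearest
macromolecule bead, calls a frame "surface" when the same partner has been
held continuously for more than 5 ns on *both* sides of the frame, records
residency segments longer than the threshold, and fits surface-population
MSD slopes with the two-dimensional divisor 4.  On a synthetic mixture of
sphere-surface walkers (angular diffusion, `D_2D = Drot R^2`) and free 3D
walkers it separates the populations and recovers both diffusivities
within 10%.

## Rotation analysis

Orientations come either from a generator (`gen_rigid_rotor()`, isotropic
small-angle rotational diffusion composed from random rotation vectors,
renormalized onto SO(3)) or from atom groups by least-RMSD superposition
(`kabsch_rotation()`, SVD construction with a determinant guard against
reflections).  The rotational correlation `rotational_correlation()`
correlates the three body-frame unit vectors (columns of the best-fit
rotation) between window start and lag, averaging over vectors, origins
and copies; for free rotational diffusion it decays as
`exp(-2 Drot tau)`, so the single-exponential fit
(`fit_rotational_relaxation()`, nonlinear least squares restricted to
`theta` in [0.1, 1]) yields `tau_rel` and `Drot = 1/(2 tau_rel)`.  A curve
that never decays below 0.9 is returned flagged with infinite `tau_rel`
rather than force-fitted.  `mean_angular_velocity()` reports
`(180/pi) arccos` of the averaged unit-vector inner product across the
observation window -- degrees per window by default, with a per-ns option,
since the angular-velocity convention is reported per observation window
in the methodology this package follows.

## Quinary interactions

`coordination_series()` counts reference beads of other molecules within
50 A of the target's beads (or 25 A of a metabolite's center of mass) and
averages over 10 ns windows advanced in 500 ps steps.
`pair_distance_change()` and `group_interaction_matrix()` implement the
distance-change statistic: `delta_d` is the center-of-mass distance
averaged over the final `tau_short` window minus the initial one; pairs
enter the group average when their initial scaled distance
`r_bar = 2 rc / (Rs_a + Rs_b)` is below a cutoff, profiles over the cutoff
are averaged across [2, 3], and uncertainty comes from 50 random
half-splits of the qualifying pairs with `SE = SD/2`.  Negative values
mean effective attraction.  Two subtleties the tests encode:

* For *free* diffusers the proximity selection itself produces a small
  outward drift (`E[delta rc]` of order `2 D_rel t / rc`, a Bessel-process
  effect), so the ideal-gas null holds only when `D t` is small against
  the resampling noise; the null fixture uses slow walkers over a short
  span for exactly that reason.
* The SD of half-sample means approximates the standard error of the
  full-sample mean itself, so `SE = SD/2` is a conservative label of
  half that dispersion; the convention is kept as the methodology defines
  it, and the matrix should be read with that calibration in mind.

On constant trajectories the matrix is exactly zero with zero SE; under
time reversal it changes sign; under uniform rescaling of coordinates and
radii the qualifying sets are unchanged and `delta_d` scales linearly.
Matrices from multiple trajectories combine with trajectory-length
weights (`combine_interaction_matrices()`).

## Spatial distributions

`accessible_volume_profile()` partitions the periodic box into voxels and
assigns each voxel center to a shell of its nearest-surface distance
(minimum over atoms of center distance minus the atom's van der Waals
radius; for coarse-grained beads, the bead radius).  Voxels inside any
atom are "excluded", shells beyond `r_max = 25 A` pool into "beyond", and
excluded + shells + beyond tile the box exactly in voxel units -- an
identity the tests check literally.  The default voxel edge is 0.5 A,
half the 0.5 A shell width: a 1 A grid aliases half-Angstrom shells by up
to about 25%, while voxel = bin/2 keeps single-sphere shell volumes within
5% of the analytic `4 pi (a + r)^2 dr`; the coarser 1 A grid convention
remains available as an argument.

`proximal_rdf()` histograms metabolite positions by nearest-surface
distance (0.5 A bins), divides by the accessible shell volume to get
`rho(r)`, and normalizes by the 20-25 A plateau density to get `g(r)`;
if the plateau band is not flat the result carries a warning, since
`rho(inf)` would then be biased, and if the plateau holds no counts at all
normalization fails loudly.  It also reports the interacting fraction
below a stated cutoff (default 8 A, matching the surface-diffusion
convention, since the per-metabolite cutoffs behind interaction
percentages are not all published).  For uniform ideal-gas metabolites
`g(r) = 1` within 5% everywhere beyond 2 A.

`density_grid3d()` accumulates ligand positions into a 1 A voxel grid in
the reference frame of a target body: each frame the body is superposed
onto the reference, the same transform maps the ligand positions (taken
relative to the body by minimum image), and an optional two-fold symmetry
map duplicates counts before normalization.  Frames whose superposition
RMSD exceeds a threshold are skipped with a log message.  Grids export as
plain-text OpenDX (`write_opendx()`).

## Structural observables

`core_rmsd_rg()` computes per-frame RMSD on a filtered core: atoms whose
mean-square fluctuation about the superposed time-mean exceeds 3.0 A^2
(proteins) or 4.0 A^2 (tRNA) are dropped and the filter/re-superpose cycle
iterates to convergence (at most 5 rounds; the methodology does not state
whether filtering was iterated, so the package iterates and stops at a
fixed point).  The thresholds are applied to mean *square* fluctuations,
matching their printed units.  The radius of gyration is over all selected
atoms, unfiltered and equal-mass.  `ligand_site_metrics()` gives the
inter-site center-of-mass distance `d_lig` and the total charge `q_tot` of
species with any particle strictly within 8 A of a site atom;
`contact_pairs()` counts cross-selection pairs within a cutoff (10 A for
protein-protein, 5 A for phosphate-site contacts) by exact brute force.

## File formats and workflow

Extended XYZ is the canonical text format (coordinates at 1e-6 A,
`Lattice`, `Time` and `Wrapped` fields per frame); binary DCD (CHARMM
layout) is written with a JSON sidecar carrying times, species labels, box
and wrapped flag so round-trips are exact, and the DCD payload is readable
by independent tools.  Species tables are TSV with a metadata comment
header (package version, seed, content hash); selections and run reports
are JSON; configurations are YAML or JSON.

`run_workflow()` drives generate - simulate - analyze pipelines from a
single validated configuration with one master seed, writes a versioned
JSON report with per-stage status, wall time and metrics, and marks later
stages skipped when an earlier one fails.  `workflow_preset()` bundles a
desk-scale demo (81 spheres), the eightfold-scaled composition, and the
LJ depletion mixture.

## Problem sizes used by the test suite

The bundled tests exercise the full pipeline at sizes a workstation core
handles comfortably: the crowded production fixture is 648 spheres at
volume fraction 0.45 for 1 microsecond of BD (125,000 steps of 8 ps,
frames every ns, first 10% discarded as equilibration); the depletion
mixtures run 300,000 steps of 0.016 ps (about 5 ns) for roughly a hundred
particles in the (18.666 A)^3 box, with the first quarter discarded;
estimator validations use 1e4-1e6 particle-steps.  Two-component mixture
particle counts follow the round(3400 A^3 / v) per-component rule with
sizes read as radii; note the nominal component volumes slightly exceed
the stated box, which the soft LJ particles tolerate -- the depletion
comparison is qualitative and robust to the size convention.

## Known limitations

* Purely repulsive spheres without hydrodynamics underestimate crowding
  slow-down: at volume fraction 0.45 the 1-microsecond production fixture
  gives `D/D0` from 0.61 (smallest species) to 0.25 (ribosome-sized), a
  one-parameter `B/Rs` coefficient near 12, i.e. roughly twice the
  published BD cytoplasm fits; stronger suppression requires attractive
  interactions, hydrodynamic coupling, or near-glassy packings outside the
  generator's admissible range.  The monotone decrease of `D` with `Rs`
  and the sub-unity ratios are robust.
* The far-field hydrodynamic path builds dense 3n x 3n matrices; it is a
  validation tool for small systems, not a production Stokesian dynamics
  engine (no near-field lubrication).
* Rotational Brownian propagation of the spheres themselves is not
  implemented; rotors exist as synthetic ground truth for the analysis
  stack, which also accepts atom-group trajectories.
* Anomalous-diffusion exponents are not fitted; the supported runs are too
  short for the exchange regime.
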