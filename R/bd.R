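#' Pair potential parameters
#'
#' The excluded-volume interaction between coarse-grained macromolecule
#' spheres is a half-harmonic repulsion acting inside a buffer of width
#' `delta` beyond sphere-sphere contact:
#' \eqn{V(r) = k/2 (r - a_i - a_j - \Delta)^2} for
#' \eqn{r < a_i + a_j + \Delta} and 0 otherwise.  With the defaults
#' `k = 10 kBT/delta^2` and `delta = 1 A` the energy at exact contact
#' (\eqn{r = a_i + a_j}) is 5 kBT.  Lennard-Jones and
#' LJ-plus-Coulomb forms are available for mixture experiments; there the
#' contact distance is `sigma_ij = a_i + a_j` and the Coulomb term uses
#' minimum-image truncation at L/2 with a relative permittivity of 80
#' (Bjerrum length 7.1 A at 298 K).
#'
#' @param form `"half_harmonic"`, `"lennard_jones"` or `"lj_coulomb"`.
#' @param k Force constant, kBT/A^2 (half-harmonic; default `10 / delta^2`).
#' @param delta Buffer width, A.
#' @param epsilon LJ well depth, kBT.
#' @param bjerrum Bjerrum length, A (Coulomb prefactor in kBT units).
#' @param lj_cutoff LJ cutoff in units of `sigma_ij`.
#' @return An object of class `"potential_params"`.
#' @export
potential_params <- function(form = c("half_harmonic", "lennard_jones",
                                      "lj_coulomb"),
                             k = NULL, delta = 1, epsilon = 0.2,
                             bjerrum = 7.1, lj_cutoff = 2.5) {
  form <- match.arg(form)
  stopifnot(delta > 0)
  if (is.null(k)) k <- 10 / delta^2
  stopifnot(k > 0, epsilon > 0, lj_cutoff > 1)
  structure(list(form = form, k = k, delta = delta, epsilon = epsilon,
                 bjerrum = bjerrum, lj_cutoff = lj_cutoff),
            class = "potential_params")
}

pot_c_list <- function(p) {
  list(form_id = match(p$form, c("half_harmonic", "lennard_jones",
                                 "lj_coulomb")) - 1L,
       k = p$k, delta = p$delta, epsilon = p$epsilon, bjerrum = p$bjerrum,
       lj_cutoff = p$lj_cutoff)
}

#' Pair energy and force of the coarse-grained potential
#'
#' @param rij Center-center distance(s), A (> 0).
#' @param ai,aj Particle radii, A.
#' @param params A [potential_params()].
#' @param qi,qj Charges in elementary charges (Coulomb form only).
#' @return List with vectors `energy` (kBT) and `force` (kBT/A, the radial
#'   force magnitude `-dV/dr`; positive = repulsive).
#' @examples
#' pair_energy(30, 10, 20, potential_params())$energy # 5 kBT at contact
#' @export
pair_energy <- function(rij, ai, aj, params = potential_params(),
                        qi = 0, qj = 0) {
  if (any(rij <= 0)) stop("singular configuration: rij must be > 0")
  n <- max(length(rij), length(ai), length(aj))
  rij <- rep_len(rij, n); ai <- rep_len(ai, n); aj <- rep_len(aj, n)
  qi <- rep_len(qi, n); qj <- rep_len(qj, n)
  e <- numeric(n); f <- numeric(n)
  for (t in seq_len(n)) {
    co <- matrix(c(0, 0, 0, rij[t], 0, 0), 2, 3, byrow = TRUE)
    res <- cpp_forces(co, c(ai[t], aj[t]), c(qi[t], qj[t]), 0,
                      pot_c_list(params), FALSE)
    e[t] <- res$energy
    f[t] <- res$forces[2, 1]
  }
  list(energy = e, force = f)
}

#' Brownian-dynamics run parameters
#'
#' Defaults follow the standard coarse-grained cytoplasm setup: 8 ps
#' timestep, 298 K, water viscosity 0.890 mPa s, second-order
#' predictor-corrector integration.
#'
#' @param timestep Timestep, ps.
#' @param temperature Temperature, K.
#' @param viscosity Solvent viscosity, mPa s.
#' @param scheme `"iniesta_delatorre"` (second-order predictor-corrector),
#'   `"ermak_mccammon"` (first order), or `"fixman_rpy"` (far-field
#'   hydrodynamics; small systems only).
#' @param seed Integer seed for the noise stream.
#' @param steps Number of BD steps.
#' @param output_stride Record every this many steps.
#' @export
bd_params <- function(timestep = 8, temperature = 298, viscosity = 0.890,
                      scheme = c("iniesta_delatorre", "ermak_mccammon",
                                 "fixman_rpy"),
                      seed = 1, steps = 1000, output_stride = 10) {
  scheme <- match.arg(scheme)
  stopifnot(timestep > 0, temperature > 0, viscosity > 0, steps >= 1,
            output_stride >= 1)
  structure(list(timestep = timestep, temperature = temperature,
                 viscosity = viscosity, scheme = scheme,
                 seed = as.integer(seed), steps = as.integer(steps),
                 output_stride = as.integer(output_stride)),
            class = "bd_params")
}

#' Suggested BD timestep from the smallest particle radius
#'
#' The timestep rule `dt = 0.0005 a_min^2 / D(a_min)` with the
#' Stokes-Einstein `D`; equivalently `0.0005 * 6 pi eta a_min^3 / kBT`.
#' For a smallest radius of about 15.8 A in water at 298 K this gives the
#' standard 8 ps step.
#'
#' @param a_min Smallest Stokes radius in the system, A (> 0).
#' @param bd A [bd_params()] supplying temperature and viscosity.
#' @return Suggested timestep in ps.
#' @examples
#' suggest_timestep(15.8) # ~8 ps
#' @export
suggest_timestep <- function(a_min, bd = bd_params()) {
  if (!is.numeric(a_min) || length(a_min) != 1 || !is.finite(a_min) ||
      a_min <= 0)
    stop("a_min must be a single positive radius")
  0.0005 * a_min^2 / stokes_einstein_D(a_min, bd$temperature, bd$viscosity)
}

#' Single Brownian-dynamics step (reference implementation)
#'
#' One Ermak-McCammon update `dx = D F dt + xi` with per-axis Gaussian noise
#' of variance `2 D dt`, or the Iniesta-de la Torre predictor-corrector that
#' reuses the same noise realization in both half-updates.  This R-level
#' step exists for validation (its noise can be switched off to expose the
#' deterministic drift); production runs use the compiled loop in
#' [run_simulation()].
#'
#' @param coords n x 3 coordinates, A.
#' @param radii Particle radii, A.
#' @param bd A [bd_params()].
#' @param potential A [potential_params()].
#' @param box A [sim_box()] or `NULL`.
#' @param charges Optional charges.
#' @param noise Logical; `FALSE` zeroes the random displacement.
#' @param forces Optional pre-computed n x 3 force matrix (kBT/A); when
#'   supplied the potential is not evaluated (Ermak scheme only).
#' @return Updated n x 3 coordinates.
#' @export
bd_step <- function(coords, radii, bd = bd_params(),
                    potential = potential_params(), box = NULL,
                    charges = NULL, noise = TRUE, forces = NULL) {
  coords <- rbind(coords)
  n <- nrow(coords)
  if (is.null(charges)) charges <- rep(0, n)
  L <- box_L(box)
  D <- stokes_einstein_D(radii, bd$temperature, bd$viscosity)
  dt <- bd$timestep
  xi <- if (noise) matrix(rnorm(3 * n), n, 3) * sqrt(2 * D * dt) else 0
  F1 <- forces %||%
    cpp_forces(coords, radii, charges, L, pot_c_list(potential))$forces
  if (!all(is.finite(F1))) stop("non-finite forces")
  drift1 <- F1 * D * dt
  if (bd$scheme == "ermak_mccammon" || !is.null(forces))
    return(coords + drift1 + xi)
  pred <- coords + drift1 + xi
  F2 <- cpp_forces(pred, radii, charges, L, pot_c_list(potential))$forces
  coords + (F1 + F2) / 2 * D * dt + xi
}

#' Run a Brownian-dynamics simulation
#'
#' Propagates a sphere system with the chosen potential and integrator and
#' returns the recorded trajectory.  The initial configuration must be free
#' of hard overlaps unless `soft_start = TRUE`, which caps forces at
#' `force_cap` so strained configurations relax instead of exploding.
#' Runs with the same seed are identical.
#'
#' @param system List with `coords` (n x 3), `box`, and either `table` plus
#'   `species_index` or a `radii` vector (plus optional `charges`) --
#'   the shape returned by [gen_packed_configuration()] and
#'   [gen_lj_mixture()].
#' @param bd A [bd_params()].
#' @param potential A [potential_params()].
#' @param soft_start Allow an overlapping start with capped forces.
#' @param force_cap Per-particle force cap in kBT/A used when
#'   `soft_start = TRUE`.
#' @return An unwrapped [trajectory()] with an `energies` attribute (kBT
#'   per recorded frame).
#' @export
run_simulation <- function(system, bd = bd_params(),
                           potential = potential_params(),
                           soft_start = FALSE, force_cap = 10) {
  coords <- rbind(system$coords)
  n <- nrow(coords)
  L <- box_L(system$box)
  if (!is.null(system$table)) {
    spi <- system$species_index %||% rep(1L, n)
    tab <- system$table
    radii <- tab$stokes_radius[spi]
    charges <- system$charges %||% tab$charge[spi]
  } else {
    radii <- system$radii
    charges <- system$charges %||% rep(0, n)
    tab <- species_table("particle", max(radii), n)
    spi <- rep(1L, n)
  }
  stopifnot(length(radii) == n)
  if (!soft_start && potential$form == "half_harmonic") {
    ov <- hard_overlaps(coords, radii, L)
    if (nrow(ov))
      stop("initial configuration has ", nrow(ov), " overlapping pair(s); ",
           "use soft_start = TRUE to relax it")
  }
  if (bd$scheme == "fixman_rpy")
    return(run_simulation_rpy(coords, radii, charges, tab, spi, system$box,
                              bd, potential))
  D <- stokes_einstein_D(radii, bd$temperature, bd$viscosity)
  cap <- if (soft_start) force_cap else Inf
  scheme <- if (bd$scheme == "ermak_mccammon") 0L else 1L
  res <- with_seed(bd$seed,
    cpp_run_bd(coords, radii, charges, L, pot_c_list(potential), D,
               bd$timestep, bd$steps, bd$output_stride, scheme, cap, TRUE))
  traj <- trajectory(res$times, res$frames, spi, tab, system$box,
                     wrapped = FALSE,
                     molecule_index = system$molecule_index %||% seq_len(n))
  attr(traj, "energies") <- res$energies
  traj
}

#' Far-field (Rotne-Prager-Yamakawa) mobility
#'
#' The pairwise far-field hydrodynamic mobility of a non-overlapping sphere
#' configuration, returned as the 3n x 3n diffusion matrix `kBT * mu` in
#' A^2/ps.  Self-blocks equal the Stokes-Einstein `kBT/(6 pi eta a_i)` times
#' the identity; the matrix is symmetric positive-definite for any
#' non-overlapping configuration.
#'
#' @param coords n x 3 coordinates, A.
#' @param radii Sphere radii, A.
#' @param viscosity Viscosity, mPa s.
#' @param temperature Temperature, K.
#' @return 3n x 3n numeric matrix (blocks ordered particle-major).
#' @export
rpy_mobility <- function(coords, radii, viscosity = 0.890,
                         temperature = 298) {
  coords <- rbind(coords)
  n <- nrow(coords)
  C <- kT_over_6pieta(temperature, viscosity)  # D * a, A^3/ps
  M <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    ii <- (3 * (i - 1) + 1):(3 * i)
    M[ii, ii] <- diag(3) * C / radii[i]
    if (i < n) for (j in (i + 1):n) {
      rij <- coords[j, ] - coords[i, ]
      r <- sqrt(sum(rij^2))
      if (r < radii[i] + radii[j])
        stop("overlapping pair (", i, ",", j, "): the far-field mobility ",
             "is only valid for non-overlapping spheres")
      rh <- rij / r
      a2 <- radii[i]^2 + radii[j]^2
      blk <- (3 / 4) * (C / r) *
        ((1 + a2 / (3 * r^2)) * diag(3) +
         (1 - a2 / r^2) * (rh %o% rh))
      jj <- (3 * (j - 1) + 1):(3 * j)
      M[ii, jj] <- blk
      M[jj, ii] <- blk
    }
  }
  M
}

# Brownian dynamics with far-field hydrodynamic coupling (small systems):
# Ermak-McCammon drift D F dt with correlated noise sqrt(2 dt) B xi,
# B Bᵀ = D, and Fixman-style midpoint re-evaluation of the mobility.
# The RPY tensor is divergence-free, so no spurious drift term is needed.
run_simulation_rpy <- function(coords, radii, charges, tab, spi, box, bd,
                               potential) {
  n <- nrow(coords)
  if (n > 100)
    stop("fixman_rpy scheme builds dense 3n x 3n mobilities; ",
         "intended for small systems (n <= 100)")
  L <- box_L(box)
  dt <- bd$timestep
  nrec <- bd$steps %/% bd$output_stride + 1
  frames <- array(0, c(nrec, n, 3))
  energies <- numeric(nrec)
  times <- numeric(nrec)
  with_seed(bd$seed, {
    x <- coords
    rec <- 1
    fr <- cpp_forces(x, radii, charges, L, pot_c_list(potential))
    frames[1, , ] <- x; energies[1] <- fr$energy; times[1] <- 0
    for (s in seq_len(bd$steps)) {
      Dm <- rpy_mobility(x, radii, bd$viscosity, bd$temperature)
      B <- t(chol(Dm))
      Fv <- as.vector(t(cpp_forces(x, radii, charges, L,
                                   pot_c_list(potential))$forces))
      xi <- sqrt(2 * dt) * as.vector(B %*% rnorm(3 * n))
      drift <- as.vector(Dm %*% Fv) * dt
      xmid <- x + t(matrix(drift / 2 + xi / 2, 3, n))
      Dmid <- tryCatch(rpy_mobility(xmid, radii, bd$viscosity,
                                    bd$temperature),
                       error = function(e) Dm)
      drift <- as.vector(Dmid %*% Fv) * dt
      x <- x + t(matrix(drift + xi, 3, n))
      if (s %% bd$output_stride == 0) {
        rec <- rec + 1
        fr <- cpp_forces(x, radii, charges, L, pot_c_list(potential))
        frames[rec, , ] <- x; energies[rec] <- fr$energy
        times[rec] <- s * dt
      }
    }
  })
  traj <- trajectory(times, frames, spi, tab, box, wrapped = FALSE)
  attr(traj, "energies") <- energies
  traj
}

#' Total potential energy and forces of a configuration
#'
#' @inheritParams bd_step
#' @param use_cells Use the cell-list neighbor search (the all-pairs path is
#'   retained as an exact oracle).
#' @return List with `energy` (kBT) and `forces` (n x 3, kBT/A).
#' @export
system_energy <- function(coords, radii, potential = potential_params(),
                          box = NULL, charges = NULL, use_cells = TRUE) {
  coords <- rbind(coords)
  if (is.null(charges)) charges <- rep(0, nrow(coords))
  cpp_forces(coords, radii, charges, box_L(box), pot_c_list(potential),
             use_cells)
}
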