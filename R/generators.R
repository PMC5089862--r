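#' Free Brownian walkers with known diffusion constant
#'
#' Generates `n` independent random walkers whose per-axis step variance is
#' exactly `2 * D_true * dt`, the ground truth for validating the MSD and
#' diffusion-fit estimators.  Pure function of its parameters and seed.
#'
#' @param n Number of walkers.
#' @param D_true True diffusion constant in A^2/ps (>= 0).
#' @param dt Frame spacing in ps (> 0).
#' @param steps Number of steps (frames = steps + 1).
#' @param seed Integer seed.
#' @param box Optional [sim_box()]; walkers start uniformly in the box and
#'   the returned trajectory is unwrapped.
#' @return An unwrapped [trajectory()].
#' @export
gen_brownian_walkers <- function(n, D_true, dt, steps, seed = 1,
                                 box = NULL) {
  if (D_true < 0) stop("D_true must be >= 0")
  stopifnot(dt > 0, n >= 1, steps >= 1)
  with_seed(seed, {
    L <- box_L(box)
    x0 <- if (L > 0) matrix(runif(3 * n, 0, L), n, 3)
          else matrix(0, n, 3)
    sdstep <- sqrt(2 * D_true * dt)
    co <- array(0, c(steps + 1, n, 3))
    co[1, , ] <- x0
    if (sdstep > 0) {
      stepsarr <- array(rnorm(steps * n * 3, sd = sdstep), c(steps, n, 3))
      cs <- apply(stepsarr, c(2, 3), cumsum)
      dim(cs) <- c(steps, n, 3)
      co[-1, , ] <- sweep(cs, c(2, 3), x0, "+")
    } else {
      for (f in 2:(steps + 1)) co[f, , ] <- x0
    }
    a <- max(1e-6, kT_over_6pieta() / max(D_true, 1e-12))
    tab <- species_table("walker", min(a, 1e4), n)
    trajectory((0:steps) * dt, co, rep(1L, n), tab, box, wrapped = FALSE)
  })
}

# skew-symmetric cross-product matrix
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Rodrigues rotation for a rotation vector w (angle = |w|)
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  K <- skew3(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# project a near-rotation onto SO(3) (closest orthonormal, det +1)
orthonormalize_rotation <- function(R) {
  s <- svd(R)
  U <- s$u; V <- s$v
  D <- diag(c(1, 1, sign(det(U %*% t(V)))))
  U %*% D %*% t(V)
}

#' Rigid rotor with known rotational diffusion constant
#'
#' Generates isotropic small-angle rotational diffusion: at each step the
#' body rotates by a random rotation vector with per-axis variance
#' `2 * Drot_true * dt`.  Orientation operators are renormalized against
#' drift from SO(3) and have determinant +1 in every frame.  The first-rank
#' orientation autocorrelation of such a rotor decays as
#' `exp(-2 * Drot_true * tau)`.
#'
#' @param Drot_true True rotational diffusion constant in rad^2/ps (>= 0).
#' @param dt Frame spacing, ps.
#' @param steps Steps per copy.
#' @param seed Integer seed.
#' @param n_copies Number of independent rotor copies.
#' @return An object of class `"orientation_track"`: times plus rotation
#'   array `c(frames, 3, 3, n_copies)`.
#' @export
gen_rigid_rotor <- function(Drot_true, dt, steps, seed = 1, n_copies = 1) {
  if (Drot_true < 0) stop("Drot_true must be >= 0")
  stopifnot(dt > 0, steps >= 1, n_copies >= 1)
  with_seed(seed, {
    rot <- array(0, c(steps + 1, 3, 3, n_copies))
    sdw <- sqrt(2 * Drot_true * dt)
    for (c in seq_len(n_copies)) {
      R <- diag(3)
      rot[1, , , c] <- R
      for (f in seq_len(steps)) {
        if (sdw > 0) {
          R <- rotvec_to_matrix(rnorm(3, sd = sdw)) %*% R
          if (max(abs(crossprod(R) - diag(3))) > 1e-9)
            R <- orthonormalize_rotation(R)
        }
        rot[f + 1, , , c] <- R
      }
    }
    structure(list(times = (0:steps) * dt, rotations = rot,
                   n_copies = n_copies, Drot_true = Drot_true),
              class = "orientation_track")
  })
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("Orientation track: %d frames x %d copies, t up to %.4g ps\n",
              length(x$times), x$n_copies, max(x$times)))
  invisible(x)
}

#' Bead trajectory of a rigidly rotating body
#'
#' Applies the rotations of an orientation track to a bead template, giving
#' an atom-group trajectory whose best-fit superposition against the
#' template must recover the applied rotations exactly.
#'
#' @param track An `orientation_track` (single copy used unless `copy`
#'   given).
#' @param template m x 3 bead coordinates (centered template recommended).
#' @param copy Which rotor copy to use.
#' @return An unwrapped [trajectory()] of the rotating beads.
#' @export
apply_rotations <- function(track, template, copy = 1) {
  template <- rbind(template)
  nf <- length(track$times)
  co <- array(0, c(nf, nrow(template), 3))
  for (f in seq_len(nf))
    co[f, , ] <- template %*% t(track$rotations[f, , , copy])
  tab <- species_table("bead", 2, nrow(template))
  trajectory(track$times, co, rep(1L, nrow(template)), tab, NULL,
             wrapped = FALSE,
             molecule_index = rep(1L, nrow(template)))
}

#' Packed overlap-free configuration of a polydisperse sphere system
#'
#' Builds an initial configuration for a species table in a periodic box:
#' copy numbers are multiplied by `scale_factor` (the eightfold rule used to
#' scale a base composition up to a production coarse-grained system), then
#' spheres are inserted largest-first by random sequential insertion with
#' rejection.  If insertion stalls at high packing the remaining spheres are
#' placed randomly and the configuration is relaxed by soft-start Brownian
#' dynamics (forces capped at 10 kBT/A) until no pair overlaps.  The
#' returned configuration satisfies `r_ij >= a_i + a_j` for every pair.
#'
#' @param table A [species_table()].
#' @param box A [sim_box()].
#' @param seed Integer seed.
#' @param scale_factor Integer copy-number multiplier.
#' @param max_attempts Insertion attempts per sphere before falling back to
#'   soft-start relaxation.
#' @param max_relax_steps Soft-start BD step budget.
#' @return List with `coords` (n x 3, wrapped), `species_index`, `table`
#'   (scaled copies), `box`.
#' @export
gen_packed_configuration <- function(table, box, seed = 1, scale_factor = 1,
                                     max_attempts = 300,
                                     max_relax_steps = 20000) {
  table <- validate_species_table(as.data.frame(table))
  table$copies <- as.integer(table$copies * scale_factor)
  phi <- volume_fraction(table, box)
  if (phi > 0.55)
    stop(sprintf(paste0("requested volume fraction %.2f exceeds 0.55; ",
                        "dense packings beyond this are not reachable"),
                 phi))
  L <- box_L(box)
  sp <- expand_species(table)
  ord <- order(sp$radius, decreasing = TRUE)
  n <- length(ord)
  with_seed(seed, {
    coords <- matrix(NA_real_, n, 3)
    placed <- 0L
    failed <- integer(0)
    for (k in seq_len(n)) {
      i <- ord[k]
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- runif(3, 0, L)
        if (placed == 0L) { ok <- TRUE; break }
        d <- min_image_dist(p, coords[ord[seq_len(placed)], , drop = FALSE],
                            L)
        if (all(d >= sp$radius[i] + sp$radius[ord[seq_len(placed)]])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) { failed <- c(failed, k); p <- runif(3, 0, L) }
      coords[i, ] <- p
      placed <- placed + 1L
    }
    if (length(failed)) {
      coords <- soft_start_relax(coords, sp$radius, L, max_relax_steps)
    }
    ov <- hard_overlaps(coords, sp$radius, L)
    if (nrow(ov))
      stop("insertion failed at volume fraction ", sprintf("%.2f", phi),
           ": ", nrow(ov), " overlapping pair(s) remain after soft-start ",
           "equilibration; increase max_relax_steps or reduce packing")
    list(coords = coords, species_index = sp$index, table = table,
         box = box)
  })
}

# pairs with center distance < ai + aj (hard overlap)
hard_overlaps <- function(coords, radii, L, tol = 0) {
  pr <- cpp_pairs_within(coords, L, 2 * max(radii))
  if (!length(pr$i)) return(data.frame(i = integer(), j = integer()))
  bad <- pr$d < radii[pr$i] + radii[pr$j] - tol
  data.frame(i = pr$i[bad], j = pr$j[bad])
}

# Capped-force BD relaxation until hard overlaps vanish: noisy chunks shake
# the configuration apart, noiseless gradient chunks then park every pair
# outside contact (the half-harmonic potential is zero beyond
# a_i + a_j + delta, so descent terminates in an overlap-free state).
soft_start_relax <- function(coords, radii, L, max_steps) {
  pot <- potential_params("half_harmonic")
  D <- stokes_einstein_D(radii)
  dt <- suggest_timestep(min(radii))
  q0 <- rep(0, length(radii))
  done <- 0L
  while (done < max_steps) {
    chunk <- as.integer(min(1000, max_steps - done))
    res <- cpp_run_bd(coords, radii, q0, L, pot_c_list(pot), D, dt,
                      chunk, chunk, 1L, 10, TRUE)
    coords <- matrix(res$frames[2, , ], ncol = 3)
    res <- cpp_run_bd(coords, radii, q0, L, pot_c_list(pot), D, dt,
                      chunk, chunk, 1L, 10, FALSE)
    coords <- matrix(res$frames[2, , ], ncol = 3)
    done <- done + 2L * chunk
    if (!nrow(hard_overlaps(coords, radii, L))) break
  }
  wrap_coords(coords, L)
}

#' Bidisperse Lennard-Jones mixtures
#'
#' The two-component mixtures used to probe depletion effects: small 'A'
#' particles (radius 2 A) mixed with a partner component -- same-size 'B',
#' or larger 'C' (3.509 A) or 'D' (5.570 A) -- where each component
#' nominally occupies 3400 A^3 in a (18.666 A)^3 cubic box.  Sizes are
#' interpreted as particle radii and per-component counts are
#' `round(3400 / v)` with `v` the single-particle volume; in `AD_rep` the
#' 'D' particles carry a unit positive charge to create repulsion.
#'
#' @param case One of `"AB"`, `"AC"`, `"AD"`, `"AD_rep"`.
#' @param seed Integer seed.
#' @param epsilon LJ well depth in kBT (default 0.2: weakly attractive,
#'   fluid at this density).
#' @return List with `coords` (relaxed, overlap-tolerant start), `table`,
#'   `species_index`, `charges`, `box`, `potential`.
#' @export
gen_lj_mixture <- function(case = c("AB", "AC", "AD", "AD_rep"), seed = 1,
                           epsilon = 0.2) {
  case <- match.arg(case)
  partner_radius <- c(AB = 2, AC = 3.509, AD = 5.570, AD_rep = 5.570)[[case]]
  partner_name <- c(AB = "B", AC = "C", AD = "D", AD_rep = "D")[[case]]
  vol <- function(r) 4 / 3 * pi * r^3
  nA <- round(3400 / vol(2))
  nP <- round(3400 / vol(partner_radius))
  qP <- if (case == "AD_rep") 1 else 0
  tab <- species_table(c("A", partner_name), c(2, partner_radius),
                       c(nA, nP), group = "metabolite",
                       charge = c(0, qP))
  box <- sim_box(18.666)
  pot <- potential_params(if (qP != 0) "lj_coulomb" else "lennard_jones",
                          epsilon = epsilon)
  sp <- expand_species(tab)
  with_seed(seed, {
    coords <- matrix(runif(3 * length(sp$index), 0, box_L(box)),
                     ncol = 3)
    # push deep random overlaps apart with capped forces before handing the
    # configuration to the caller
    D <- stokes_einstein_D(sp$radius)
    res <- cpp_run_bd(coords, sp$radius, sp$charge, box_L(box),
                      pot_c_list(pot), D, 0.002, 2000L, 2000L, 1L, 10,
                      TRUE)
    coords <- wrap_coords(matrix(res$frames[2, , ], ncol = 3), box)
    list(coords = coords, table = tab, species_index = sp$index,
         charges = sp$charge, box = box, potential = pot)
  })
}

#' Toy bead-macromolecule plus metabolite systems
#'
#' A small fixture generator for the spatial and structural metrics:
#' `n_macromolecules` rigid bead clusters (a tetrahedral 4-bead core plus
#' two single-bead ligand sites) and `n_metabolites` point metabolites, a
#' configurable fraction of which is placed uniformly in the box (an ideal
#' gas, for which the proximal distribution function is flat at 1).
#'
#' @param n_macromolecules,n_metabolites Counts (>= 1).
#' @param seed Integer seed.
#' @param n_frames Frames to emit (static configuration repeated, with
#'   optional per-frame jitter).
#' @param uniform_fraction Fraction of metabolites placed uniformly; the
#'   remainder is placed in contact with a macromolecule surface.
#' @param box_edge Box edge, A.
#' @param bead_radius Macromolecule bead radius, A.
#' @param jitter Per-frame Gaussian jitter amplitude, A.
#' @return List with `traj` (wrapped [trajectory()]) and `selections`
#'   (per-macromolecule [atom_group_selection()]s plus a metabolite
#'   selection).
#' @export
gen_toy_cell <- function(n_macromolecules, n_metabolites, seed = 1,
                         n_frames = 1, uniform_fraction = 1,
                         box_edge = 60, bead_radius = 2, jitter = 0) {
  stopifnot(n_macromolecules >= 1, n_metabolites >= 1,
            uniform_fraction >= 0, uniform_fraction <= 1)
  with_seed(seed, {
    L <- box_edge
    # tetrahedral core + two site beads, edge ~ 4 A
    template <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                      c(-1, -1, 1), c(3, 0, 0), c(-3, 0, 0)) * 2
    nb <- nrow(template)
    coords <- NULL
    mol <- integer(0)
    sels <- list()
    centers <- matrix(runif(3 * n_macromolecules, 0.2 * L, 0.8 * L),
                      ncol = 3)
    for (m in seq_len(n_macromolecules)) {
      R <- orthonormalize_rotation(matrix(rnorm(9), 3, 3))
      beads <- sweep(template %*% t(R), 2, centers[m, ], "+")
      off <- nrow(coords %||% matrix(0, 0, 3))
      coords <- rbind(coords, beads)
      mol <- c(mol, rep(m, nb))
      sels[[length(sels) + 1]] <- atom_group_selection(
        sprintf("macro%d_core", m), off + 1:4, "core")
      sels[[length(sels) + 1]] <- atom_group_selection(
        sprintf("macro%d_site1", m), off + 5L, "ligand_site_1")
      sels[[length(sels) + 1]] <- atom_group_selection(
        sprintf("macro%d_site2", m), off + 6L, "ligand_site_2")
    }
    n_macro_beads <- nrow(coords)
    n_uni <- round(uniform_fraction * n_metabolites)
    mets <- matrix(runif(3 * n_uni, 0, L), ncol = 3)
    if (n_uni < n_metabolites) {
      for (k in seq_len(n_metabolites - n_uni)) {
        m <- sample.int(n_macromolecules, 1)
        b <- sample.int(nb, 1)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        base <- coords[(m - 1) * nb + b, ]
        mets <- rbind(mets, base + dir * (bead_radius + 1))
      }
    }
    coords <- rbind(coords, mets)
    mol <- c(mol, n_macromolecules + seq_len(n_metabolites))
    tab <- species_table(c("macro_bead", "metabolite"),
                         c(bead_radius, 1),
                         c(n_macro_beads, n_metabolites),
                         group = c("protein", "metabolite"))
    spi <- c(rep(1L, n_macro_beads), rep(2L, n_metabolites))
    co <- array(0, c(n_frames, nrow(coords), 3))
    for (f in seq_len(n_frames)) {
      jit <- if (jitter > 0 && f > 1)
        matrix(rnorm(length(coords), sd = jitter), ncol = 3) else 0
      co[f, , ] <- wrap_coords(coords + jit, L)
    }
    sels[[length(sels) + 1]] <- atom_group_selection(
      "metabolites", n_macro_beads + seq_len(n_metabolites),
      "reference_atoms")
    traj <- trajectory((seq_len(n_frames) - 1) * 10, co, spi, tab,
                       sim_box(L), wrapped = TRUE, molecule_index = mol)
    list(traj = traj, selections = sels)
  })
}
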