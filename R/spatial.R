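#' Voxel-based accessible volume profile
#'
#' The periodic box is divided into cubic voxels (1 A default); every voxel
#' center is assigned to the shell of its nearest-surface distance (minimum
#' over macromolecule atoms of center distance minus the atom's van der
#' Waals radius).  Voxels inside any atom are excluded; shells beyond
#' `r_max` are pooled.  The excluded volume, all shells and the beyond-pool
#' together tile the box exactly, voxel by voxel.
#'
#' @param atoms n x 3 macromolecule atom coordinates (one frame), or an
#'   unselected [trajectory()] plus `frames`/`selection` to average over.
#' @param radii Per-atom van der Waals radii, A (for coarse-grained beads:
#'   the bead radius; 0 gives atom-center shells).
#' @param box A [sim_box()].
#' @param voxel Voxel edge, A; the default (half the shell width) keeps
#'   shell volumes converged at the bin resolution, while `voxel = 1`
#'   reproduces the coarser 1 A grid convention.
#' @param r_max Profile truncation, A (default 25, past the normalization
#'   plateau).
#' @param bin Shell width, A.
#' @return data.frame of class `"accessible_volume"` with `r` (shell lower
#'   edge) and `V` (A^3), attributes `excluded`, `beyond`, `box_volume`
#'   (all in A^3) and `voxel`.
#' @export
accessible_volume_profile <- function(atoms, radii, box, voxel = 0.5,
                                      r_max = 25, bin = 0.5) {
  atoms <- rbind(atoms)
  if (!nrow(atoms)) stop("no macromolecule atoms")
  radii <- rep_len(radii, nrow(atoms))
  L <- box_L(box)
  stopifnot(L > 0)
  res <- cpp_voxel_profile(atoms, radii, L, voxel, r_max, bin)
  v3 <- (L / res$n_grid)^3
  nb <- length(res$V_voxels)
  out <- data.frame(r = (seq_len(nb) - 1) * bin, V = res$V_voxels * v3)
  structure(out, excluded = res$excluded * v3, beyond = res$beyond * v3,
            box_volume = res$n_grid^3 * v3, voxel = L / res$n_grid,
            voxel_counts = res$V_voxels,
            excluded_voxels = res$excluded, beyond_voxels = res$beyond,
            class = c("accessible_volume", "data.frame"))
}

#' Proximal radial distribution function
#'
#' Distribution of metabolite positions as a function of the distance to
#' the NEAREST macromolecule surface, normalized by the accessible volume
#' of each distance shell and by the far-field density:
#' `g(r) = n(r) / (V(r) * rho_inf)`, with `rho_inf` the mean density over
#' the 20-25 A plateau.  Also reports the interacting fraction: the share
#' of metabolite positions with nearest-surface distance below
#' `interaction_cutoff`.
#'
#' @param traj A [trajectory()] containing both metabolites and
#'   macromolecule beads.
#' @param metabolite_selection,macromolecule_selection Particle indices or
#'   species names.
#' @param radii Optional per-atom van der Waals radii for the
#'   macromolecule selection (default: bead Stokes radii from the table).
#' @param plateau Normalization range `c(lo, hi)` in A (default 20-25).
#' @param bin Histogram bin width, A (default 0.5).
#' @param r_max Profile truncation, A.
#' @param voxel Voxel edge for the accessible volume, A.
#' @param frames Frame indices to accumulate (default: all).
#' @param interaction_cutoff Cutoff for the interacting fraction, A.
#' @return Object of class `"proximal_rdf"`: data.frame with `r`, `n`,
#'   `V`, `rho`, `g`; attributes `rho_inf`, `interacting_fraction`,
#'   `plateau_flat` (warning flag when the plateau band is not flat).
#' @export
proximal_rdf <- function(traj, metabolite_selection,
                         macromolecule_selection, radii = NULL,
                         plateau = c(20, 25), bin = 0.5, r_max = NULL,
                         voxel = 0.5, frames = NULL,
                         interaction_cutoff = 8) {
  if (is.null(r_max)) r_max <- plateau[2]
  if (plateau[2] > r_max) stop("plateau range must lie within r_max")
  met <- resolve_selection(traj, metabolite_selection)
  mac <- resolve_selection(traj, macromolecule_selection)
  if (!length(met) || !length(mac)) stop("empty selection")
  L <- box_L(traj$box)
  if (is.null(radii))
    radii <- traj$table$stokes_radius[traj$species_index[mac]]
  radii <- rep_len(radii, length(mac))
  frames <- frames %||% seq_len(n_frames(traj))
  nb <- as.integer(ceiling(r_max / bin))
  counts <- numeric(nb); Vsum <- numeric(nb)
  n_inter <- 0; n_tot <- 0
  for (f in frames) {
    macf <- matrix(traj$coords[f, mac, ], ncol = 3)
    metf <- matrix(traj$coords[f, met, ], ncol = 3)
    d <- cpp_nearest_surface(metf, macf, radii, L)$dist
    n_tot <- n_tot + length(d)
    n_inter <- n_inter + sum(d < interaction_cutoff)
    b <- floor(d / bin) + 1
    ok <- b >= 1 & b <= nb
    counts <- counts + tabulate(b[ok], nb)
    av <- accessible_volume_profile(macf, radii, traj$box, voxel, r_max,
                                    bin)
    Vsum <- Vsum + av$V
  }
  V <- Vsum / length(frames)
  nbar <- counts / length(frames)
  rho <- ifelse(V > 0, nbar / V, NA_real_)
  r_lo <- (seq_len(nb) - 1) * bin
  pl <- which(r_lo >= plateau[1] & r_lo < plateau[2] & is.finite(rho))
  if (!length(pl) || !any(nbar[pl] > 0))
    stop("no counts in the normalization plateau (", plateau[1], "-",
         plateau[2], " A); cannot normalize")
  rho_inf <- mean(rho[pl])
  # flatness check of the plateau band: relative slope across the band
  flat <- TRUE
  if (length(pl) > 2 && rho_inf > 0) {
    sl <- unname(coef(stats::lm(rho[pl] ~ r_lo[pl]))[2])
    flat <- abs(sl * diff(range(r_lo[pl]))) < 0.2 * rho_inf
    if (!flat)
      warning("density not flat across the ", plateau[1], "-", plateau[2],
              " A plateau; rho_inf (and hence g) may be biased")
  }
  out <- data.frame(r = r_lo, n = nbar, V = V, rho = rho,
                    g = rho / rho_inf)
  structure(out, rho_inf = rho_inf,
            interacting_fraction = n_inter / n_tot,
            interaction_cutoff = interaction_cutoff,
            plateau = plateau, plateau_flat = flat,
            class = c("proximal_rdf", "data.frame"))
}

#' @export
plot.proximal_rdf <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "s", xlab = "nearest-surface r (A)",
                 ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Three-dimensional ligand density grid around a target body
#'
#' Accumulates ligand positions into a cubic voxel grid in the reference
#' frame of a target body: each frame the target is superposed onto the
#' reference coordinates (best-fit rotation + translation), the same
#' transform is applied to the ligand positions (taken relative to the
#' target by the minimum image), and voxels are incremented.  An optional
#' two-fold symmetry map duplicates counts through a rotation/translation
#' before normalization.  Frames whose superposition RMSD exceeds
#' `rmsd_max` are skipped with a message.
#'
#' @param traj A [trajectory()].
#' @param target_selection Indices of the target body's beads.
#' @param ligand_selection Indices of the ligand particles.
#' @param reference m x 3 reference coordinates of the target (default:
#'   first frame).
#' @param extent Half-width of the grid around the reference centroid, A.
#' @param voxel Voxel edge, A (default 1).
#' @param symmetry Optional `list(R = 3x3, t = 3-vector)` applied in the
#'   reference frame to duplicate counts.
#' @param rmsd_max Superposition quality threshold, A.
#' @return Object of class `"density_grid"`: 3D array of number densities
#'   (A^-3) with metadata attributes (`counts`, `voxel`, `origin`,
#'   `frames_used`).
#' @export
density_grid3d <- function(traj, target_selection, ligand_selection,
                           reference = NULL, extent = 20, voxel = 1,
                           symmetry = NULL, rmsd_max = 5) {
  tsel <- resolve_selection(traj, target_selection)
  lsel <- resolve_selection(traj, ligand_selection)
  if (length(tsel) < 3) stop("target body needs >= 3 beads")
  L <- box_L(traj$box)
  ref <- rbind(reference %||% matrix(traj$coords[1, tsel, ], ncol = 3))
  refc <- colMeans(ref)
  ng <- as.integer(ceiling(2 * extent / voxel))
  origin <- refc - extent
  counts <- array(0, c(ng, ng, ng))
  used <- 0L
  for (f in seq_len(n_frames(traj))) {
    tco <- matrix(traj$coords[f, tsel, ], ncol = 3)
    # make the body whole across the periodic boundary before superposing
    tco <- sweep(min_image_disp(sweep(tco, 2, tco[1, ]), L), 2, tco[1, ],
                 "+")
    R <- kabsch_rotation(tco, ref)
    cen <- colMeans(tco)
    fit <- sweep(sweep(tco, 2, cen) %*% t(R), 2, refc, "+")
    rmsd <- sqrt(mean(rowSums((fit - ref)^2)))
    if (rmsd > rmsd_max) {
      message("frame ", f, " skipped: superposition RMSD ",
              sprintf("%.2f", rmsd), " A")
      next
    }
    used <- used + 1L
    lig <- matrix(traj$coords[f, lsel, ], ncol = 3)
    rel <- min_image_disp(sweep(lig, 2, cen), L)
    pos <- sweep(rel %*% t(R), 2, refc, "+")
    allpos <- pos
    if (!is.null(symmetry))
      allpos <- rbind(pos, sweep(pos %*% t(symmetry$R), 2,
                                 symmetry$t %||% c(0, 0, 0), "+"))
    ix <- floor(sweep(allpos, 2, origin) / voxel) + 1
    ok <- rowSums(ix >= 1 & ix <= ng) == 3
    for (k in which(ok))
      counts[ix[k, 1], ix[k, 2], ix[k, 3]] <-
        counts[ix[k, 1], ix[k, 2], ix[k, 3]] + 1
  }
  if (!used) stop("no frame could be superposed on the reference")
  dens <- counts / (used * voxel^3)
  structure(dens, counts = counts, voxel = voxel, origin = origin,
            frames_used = used, class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(paste0("Density grid: %d x %d x %d voxels (%.3g A), ",
                     "%d frames, peak %.4g A^-3\n"),
              d[1], d[2], d[3], attr(x, "voxel"), attr(x, "frames_used"),
              max(x)))
  invisible(x)
}

#' Write a density grid as an OpenDX scalar field
#'
#' Plain-text OpenDX format readable by common molecular viewers.
#'
#' @param grid A [density_grid3d()] result.
#' @param path Output path.
#' @export
write_opendx <- function(grid, path) {
  d <- dim(grid)
  o <- attr(grid, "origin")
  v <- attr(grid, "voxel")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2],
            d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0 0", v),
    sprintf("delta 0 %.6f 0", v),
    sprintf("delta 0 0 %.6f", v),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2],
            d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), prod(d))), con)
  vals <- as.vector(aperm(unclass(grid), c(3, 2, 1)))  # x fastest last
  idx <- seq(1, length(vals), by = 3)
  lines <- vapply(idx, function(i)
    paste(sprintf("%.6e", vals[i:min(i + 2, length(vals))]),
          collapse = " "), "")
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
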