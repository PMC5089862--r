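#' Core RMSD, RMSF and radius of gyration
#'
#' Per-frame RMSD against a reference after best-fit superposition,
#' computed on a "core" of conformationally stable atoms: atoms whose mean
#' square fluctuation about the superposed time-mean structure exceeds the
#' threshold (3.0 A^2 for proteins, 4.0 A^2 for tRNA) are removed and the
#' filter/re-superpose cycle is iterated to convergence (at most
#' `max_iter` rounds).  The radius of gyration is computed over ALL
#' selected atoms, unfiltered, with equal masses.
#'
#' @param traj A [trajectory()].
#' @param reference m x 3 reference coordinates matching the selection.
#' @param kind `"protein"` (RMSF threshold 3.0 A^2) or `"tRNA"` (4.0 A^2).
#' @param selection Particle indices (default: all).
#' @param rmsf_threshold Override the kind-based threshold, A^2.
#' @param max_iter Maximum filter/re-superpose iterations.
#' @return Object of class `"structure_metrics"`: per-frame `rmsd` and
#'   `rg` (A), per-atom `rmsf` (A^2), logical `core` mask.
#' @export
core_rmsd_rg <- function(traj, reference, kind = c("protein", "tRNA"),
                         selection = NULL, rmsf_threshold = NULL,
                         max_iter = 5) {
  kind <- match.arg(kind)
  thr <- rmsf_threshold %||% c(protein = 3.0, tRNA = 4.0)[[kind]]
  idx <- resolve_selection(traj, selection)
  ref <- rbind(reference)
  if (nrow(ref) != length(idx))
    stop("reference and selection differ in atom count")
  nf <- n_frames(traj)
  m <- length(idx)
  get_frame <- function(f) matrix(traj$coords[f, idx, ], ncol = 3)
  superpose_all <- function(core) {
    refc <- sweep(ref[core, , drop = FALSE], 2,
                  colMeans(ref[core, , drop = FALSE]))
    out <- array(0, c(nf, m, 3))
    for (f in seq_len(nf)) {
      co <- get_frame(f)
      cc <- colMeans(co[core, , drop = FALSE])
      R <- kabsch_rotation(co[core, , drop = FALSE],
                           ref[core, , drop = FALSE])
      out[f, , ] <- sweep(sweep(co, 2, cc) %*% t(R), 2,
                          colMeans(ref[core, , drop = FALSE]), "+")
    }
    out
  }
  core <- rep(TRUE, m)
  rmsf <- rep(0, m)
  for (it in seq_len(max_iter)) {
    fitted <- superpose_all(core)
    mean_str <- apply(fitted, c(2, 3), mean)
    rmsf <- rowMeans(vapply(seq_len(nf), function(f)
      rowSums((matrix(fitted[f, , ], ncol = 3) - mean_str)^2),
      numeric(m)))
    new_core <- rmsf <= thr
    if (sum(new_core) < 3)
      stop("fewer than 3 core atoms remain after RMSF filtering")
    if (identical(new_core, core)) break
    core <- new_core
  }
  fitted <- superpose_all(core)
  rmsd <- vapply(seq_len(nf), function(f) {
    dd <- matrix(fitted[f, core, ], ncol = 3) - ref[core, , drop = FALSE]
    sqrt(mean(rowSums(dd^2)))
  }, numeric(1))
  rg <- vapply(seq_len(nf), function(f) {
    co <- get_frame(f)
    sqrt(mean(rowSums(sweep(co, 2, colMeans(co))^2)))
  }, numeric(1))
  structure(list(rmsd = rmsd, rg = rg, rmsf = rmsf, core = core,
                 threshold = thr, kind = kind, times = traj$times),
            class = "structure_metrics")
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf(paste0("Structure metrics (%s): mean RMSD %.3f A, mean Rg ",
                     "%.3f A, core %d/%d atoms (RMSF <= %.1f A^2)\n"),
              x$kind, mean(x$rmsd), mean(x$rg), sum(x$core),
              length(x$core), x$threshold))
  invisible(x)
}

#' Ligand-site distance and bound charge
#'
#' `d_lig` is the per-frame distance between the centers of mass of the two
#' ligand-binding site selections.  `q_tot` is the per-frame total charge
#' of the charged species having any particle strictly within
#' `site_cutoff` of any site atom (both sites).
#'
#' @param traj A [trajectory()].
#' @param site1,site2 [atom_group_selection()]s (or index vectors).
#' @param charged_species Data frame with columns `molecule` (molecule id
#'   in `traj$molecule_index`) and `charge`, or `NULL` to use table
#'   charges of all metabolite/ion molecules.
#' @param site_cutoff Strict distance cutoff, A (default 8).
#' @return data.frame with `time`, `d_lig` (A) and `q_tot` (e).
#' @export
ligand_site_metrics <- function(traj, site1, site2, charged_species = NULL,
                                site_cutoff = 8) {
  s1 <- resolve_selection(traj, site1)
  s2 <- resolve_selection(traj, site2)
  if (!length(s1) || !length(s2)) stop("empty ligand site selection")
  L <- box_L(traj$box)
  if (is.null(charged_species)) {
    spi <- traj$species_index
    mols <- unique(traj$molecule_index[traj$table$group[spi] %in%
                                         c("metabolite", "ion")])
    charged_species <- data.frame(
      molecule = mols,
      charge = traj$table$charge[spi[match(mols, traj$molecule_index)]])
  }
  nf <- n_frames(traj)
  site_atoms <- c(s1, s2)
  d_lig <- numeric(nf); q_tot <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    c1 <- colMeans(co[s1, , drop = FALSE])
    c2 <- colMeans(co[s2, , drop = FALSE])
    d_lig[f] <- sqrt(sum(min_image_disp(c1 - c2, L)^2))
    q <- 0
    for (k in seq_len(nrow(charged_species))) {
      mi <- which(traj$molecule_index == charged_species$molecule[k])
      if (!length(mi)) next
      d <- min_image_dist(co[mi, , drop = FALSE],
                          co[site_atoms, , drop = FALSE], L)
      if (min(d) < site_cutoff) q <- q + charged_species$charge[k]
    }
    q_tot[f] <- q
  }
  data.frame(time = traj$times, d_lig = d_lig, q_tot = q_tot)
}

#' Cross-selection contact pairs per frame
#'
#' Number of atom pairs (one atom from each selection) within the cutoff,
#' per frame, under the minimum-image convention.  The two selections must
#' be disjoint.
#'
#' @param traj A [trajectory()].
#' @param selectionA,selectionB Disjoint particle selections.
#' @param cutoff Contact cutoff, A (10 for protein-protein contacts, 5 for
#'   phosphate-site contacts).
#' @return data.frame with `time` and `contacts`.
#' @export
contact_pairs <- function(traj, selectionA, selectionB, cutoff) {
  a <- resolve_selection(traj, selectionA)
  b <- resolve_selection(traj, selectionB)
  if (length(intersect(a, b)))
    stop("selections overlap; contact pairs require disjoint selections")
  L <- box_L(traj$box)
  n <- vapply(seq_len(n_frames(traj)), function(f)
    cpp_cross_pairs(matrix(traj$coords[f, a, ], ncol = 3),
                    matrix(traj$coords[f, b, ], ncol = 3), L, cutoff),
    integer(1))
  data.frame(time = traj$times, contacts = n)
}

#' Radius of gyration of a coordinate set
#'
#' Equal-mass radius of gyration about the centroid.
#'
#' @param coords m x 3 coordinates, A.
#' @return Rg in A.
#' @examples
#' radius_of_gyration(rbind(c(-1, 0, 0), c(1, 0, 0))) # 1
#' @export
radius_of_gyration <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 2) stop("need at least 2 atoms")
  sqrt(mean(rowSums(sweep(coords, 2, colMeans(coords))^2)))
}
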