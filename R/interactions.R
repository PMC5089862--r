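#' Coordination number of crowders around a target
#'
#' The instantaneous coordination number counts reference atoms (beads) of
#' OTHER macromolecules within `cutoff` of the target's own reference atoms
#' (minimum over the target's atoms; macromolecule mode, default cutoff
#' 50 A) or within `cutoff` of the target's center of mass (metabolite
#' mode, default 25 A).  Instantaneous values are then averaged over
#' windows of length `window` advanced in `stride` steps.
#'
#' @param traj A [trajectory()] (wrapped or unwrapped; distances use the
#'   minimum image).
#' @param target Molecule id (value of `traj$molecule_index`) of the target.
#' @param reference_atoms Optional particle indices to count as reference
#'   atoms (default: all particles not belonging to the target).
#' @param cutoff Cutoff, A (50 macromolecule mode, 25 metabolite mode).
#' @param window,stride Time-averaging window and stride, ps (10 ns / 500
#'   ps presets in crowded analyses); `window = 0` returns instantaneous
#'   values.
#' @param mode `"macromolecule"` (min over target beads) or `"metabolite"`
#'   (target center of mass).
#' @return Object of class `"coordination_series"`: data.frame with `time`
#'   and `Nc` (window-averaged), instantaneous series as an attribute.
#' @export
coordination_series <- function(traj, target, reference_atoms = NULL,
                                cutoff = 50, window = 10000, stride = 500,
                                mode = c("macromolecule", "metabolite")) {
  mode <- match.arg(mode)
  tidx <- which(traj$molecule_index == target)
  if (!length(tidx)) stop("no particles belong to target molecule ", target)
  ref <- reference_atoms %||% setdiff(seq_len(n_particles(traj)), tidx)
  ref <- setdiff(ref, tidx)
  if (!length(ref)) stop("empty reference selection")
  L <- box_L(traj$box)
  nf <- n_frames(traj)
  inst <- numeric(nf)
  for (f in seq_len(nf)) {
    refco <- matrix(traj$coords[f, ref, ], ncol = 3)
    probe <- if (mode == "metabolite")
      rbind(colMeans(matrix(traj$coords[f, tidx, ], ncol = 3)))
    else matrix(traj$coords[f, tidx, ], ncol = 3)
    d <- min_image_dist(refco, probe, L)
    inst[f] <- sum(apply(d, 1, min) <= cutoff)
  }
  times <- traj$times
  if (window <= 0 || nf < 2) {
    out <- data.frame(time = times, Nc = inst)
  } else {
    dtf <- times[2] - times[1]
    wlen <- max(1L, as.integer(round(window / dtf)))
    step <- max(1L, as.integer(round(stride / dtf)))
    starts <- seq(1L, nf - wlen + 1L, by = step)
    out <- data.frame(
      time = times[starts] + (wlen - 1) * dtf / 2,
      Nc = vapply(starts, function(s) mean(inst[s:(s + wlen - 1L)]),
                  numeric(1)))
  }
  structure(out, instantaneous = data.frame(time = times, Nc = inst),
            cutoff = cutoff, window = window, stride = stride, mode = mode,
            class = c("coordination_series", "data.frame"))
}

# center-of-mass time series of one molecule (n_frames x 3)
molecule_com <- function(traj, mol) {
  idx <- which(traj$molecule_index == mol)
  if (!length(idx)) stop("unknown molecule id ", mol)
  if (length(idx) == 1) matrix(traj$coords[, idx, ], ncol = 3)
  else apply(traj$coords[, idx, , drop = FALSE], c(1, 3), mean)
}

#' Center-of-mass distance change of a molecule pair
#'
#' `delta_d` is the time-averaged center-of-mass distance over the final
#' `tau_short` window minus the average over the initial `tau_short`
#' window; the scaled (dimensionless) distance is
#' `r_bar = 2 r_c / (Rs_alpha + Rs_beta)`.
#'
#' @param traj A [trajectory()].
#' @param alpha,beta Molecule ids.
#' @param tau_short Averaging window at the trajectory ends, ps (must be
#'   below half the span).
#' @return Object of class `"pair_distance_record"`: list with `delta_d`
#'   (A), `r_bar_initial`, `rc_initial`, `rc_final` and the inputs.
#' @export
pair_distance_change <- function(traj, alpha, beta, tau_short) {
  span <- traj$times[n_frames(traj)] - traj$times[1]
  if (tau_short >= span / 2)
    stop("tau_short must be below half the trajectory span")
  L <- box_L(traj$box)
  ca <- molecule_com(traj, alpha)
  cb <- molecule_com(traj, beta)
  d <- sqrt(rowSums(min_image_disp(ca - cb, L)^2))
  tt <- traj$times - traj$times[1]
  ini <- tt <= tau_short
  fin <- tt >= span - tau_short
  rs <- traj$table$stokes_radius
  ra <- rs[traj$species_index[which(traj$molecule_index == alpha)[1]]]
  rb <- rs[traj$species_index[which(traj$molecule_index == beta)[1]]]
  rc0 <- mean(d[ini]); rc1 <- mean(d[fin])
  structure(list(alpha = alpha, beta = beta,
                 rc_initial = rc0, rc_final = rc1,
                 delta_d = rc1 - rc0,
                 r_bar_initial = 2 * rc0 / (ra + rb),
                 tau_short = tau_short),
            class = "pair_distance_record")
}

#' @export
print.pair_distance_record <- function(x, ...) {
  cat(sprintf("Pair (%s, %s): delta_d = %+.3f A (r_bar initial %.3f)\n",
              x$alpha, x$beta, x$delta_d, x$r_bar_initial))
  invisible(x)
}

#' Group-level quinary interaction matrix
#'
#' For every pair of macromolecule groups, the mean center-of-mass distance
#' change `delta_d_AB`: pairs qualify when their initial scaled distance
#' `r_bar` is below `Rcut`; the group average is computed on a grid of
#' `Rcut` values and then averaged over `Rcut` in `[2, 3]` to reduce noise
#' (a scaled cutoff of 3 corresponds to pairs separated by about one
#' diameter).  Uncertainty comes from repeated random splits of the
#' qualifying pairs into halves (50 repeats, both halves kept, standard
#' error = SD/2).  Negative values indicate effective attraction.
#'
#' @param traj A [trajectory()] whose table carries group labels.
#' @param tau_short End-window average length, ps.
#' @param Rcut_range Range of scaled cutoffs to average over.
#' @param Rcut_grid Number of grid points across `Rcut_range`.
#' @param n_resample Number of random half-splits.
#' @param groups Group labels to include.
#' @param instantaneous Use the instantaneous initial distance rather than
#'   the `tau_short`-averaged one for the selection rule.
#' @param seed Seed for the resampling.
#' @return Object of class `"interaction_matrix"`: symmetric matrices
#'   `delta_d` and `se` (A; `NA` where no pair qualifies), plus per-Rcut
#'   profiles.
#' @export
group_interaction_matrix <- function(traj, tau_short,
                                     Rcut_range = c(2, 3),
                                     Rcut_grid = 5, n_resample = 50,
                                     groups = c("glycolytic", "protein",
                                                "RNA", "huge"),
                                     instantaneous = FALSE, seed = 1) {
  tab <- traj$table
  mols <- unique(traj$molecule_index)
  first_particle <- match(mols, traj$molecule_index)
  mol_group <- tab$group[traj$species_index[first_particle]]
  mol_rs <- tab$stokes_radius[traj$species_index[first_particle]]
  keep <- mol_group %in% groups
  mols <- mols[keep]; mol_group <- mol_group[keep]; mol_rs <- mol_rs[keep]
  if (length(mols) < 2) stop("fewer than two molecules in selected groups")
  L <- box_L(traj$box)
  tt <- traj$times - traj$times[1]
  span <- tt[length(tt)]
  if (tau_short >= span / 2)
    stop("tau_short must be below half the trajectory span")
  ini <- which(tt <= tau_short)
  fin <- which(tt >= span - tau_short)
  if (instantaneous) ini <- ini[1]
  coms <- lapply(mols, function(m) molecule_com(traj, m))
  n <- length(mols)
  pr <- data.frame()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(rowSums(min_image_disp(coms[[i]] - coms[[j]], L)^2))
    rc0 <- mean(d[ini]); rc1 <- mean(d[fin])
    pr <- rbind(pr, data.frame(
      gi = mol_group[i], gj = mol_group[j],
      rbar0 = 2 * rc0 / (mol_rs[i] + mol_rs[j]),
      dd = rc1 - rc0))
  }
  rcuts <- seq(Rcut_range[1], Rcut_range[2], length.out = Rcut_grid)
  gp <- sort(unique(c(pr$gi, pr$gj)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = ":")
  pr$pairkey <- key(pr$gi, pr$gj)
  mean_dd <- function(rows) {
    # average over the Rcut grid of the mean delta_d of qualifying pairs
    v <- vapply(rcuts, function(rc) {
      q <- rows$rbar0 < rc
      if (!any(q)) NA_real_ else mean(rows$dd[q])
    }, numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  dd <- matrix(NA_real_, length(gp), length(gp),
               dimnames = list(gp, gp))
  se <- dd
  profiles <- list()
  with_seed(seed, {
    for (a in seq_along(gp)) for (b in a:length(gp)) {
      rows <- pr[pr$pairkey == key(gp[a], gp[b]), , drop = FALSE]
      if (!nrow(rows)) next
      q_any <- rows$rbar0 < max(rcuts)
      if (!any(q_any)) next          # flagged absent, not zero
      dd[a, b] <- dd[b, a] <- mean_dd(rows)
      profiles[[key(gp[a], gp[b])]] <- data.frame(
        Rcut = rcuts,
        delta_d = vapply(rcuts, function(rc) {
          q <- rows$rbar0 < rc
          if (!any(q)) NA_real_ else mean(rows$dd[q])
        }, numeric(1)))
      m <- nrow(rows)
      if (m >= 2) {
        halves <- numeric(0)
        for (r in seq_len(n_resample)) {
          perm <- sample.int(m)
          h1 <- perm[seq_len(m %/% 2)]
          h2 <- perm[(m %/% 2 + 1):m]
          halves <- c(halves, mean_dd(rows[h1, , drop = FALSE]),
                      mean_dd(rows[h2, , drop = FALSE]))
        }
        se[a, b] <- se[b, a] <- stats::sd(halves, na.rm = TRUE) / 2
      }
    }
  })
  structure(list(delta_d = dd, se = se, profiles = profiles,
                 n_pairs = table(pr$pairkey), tau_short = tau_short,
                 Rcut_range = Rcut_range),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Group interaction matrix delta_d_AB (A), SE in parentheses:\n")
  gp <- rownames(x$delta_d)
  for (a in seq_along(gp)) for (b in a:length(gp)) {
    if (is.na(x$delta_d[a, b])) next
    cat(sprintf("  %-11s %-11s %+8.3f (%.3f)\n", gp[a], gp[b],
                x$delta_d[a, b], x$se[a, b]))
  }
  invisible(x)
}

#' Combine interaction matrices from several trajectories
#'
#' Weighted average of group matrices with trajectory-length weights.
#'
#' @param matrices List of [group_interaction_matrix()] results.
#' @param weights Trajectory lengths (or any weights).
#' @return An `"interaction_matrix"` with combined `delta_d` and `se`.
#' @export
combine_interaction_matrices <- function(matrices, weights) {
  stopifnot(length(matrices) == length(weights), length(matrices) >= 1)
  gp <- rownames(matrices[[1]]$delta_d)
  dd <- matrix(0, length(gp), length(gp), dimnames = list(gp, gp))
  wsum <- dd; sesq <- dd
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    ok <- !is.na(m$delta_d)
    dd[ok] <- dd[ok] + weights[k] * m$delta_d[ok]
    sesq[ok] <- sesq[ok] + (weights[k] * m$se[ok])^2
    wsum[ok] <- wsum[ok] + weights[k]
  }
  dd <- dd / wsum
  se <- sqrt(sesq) / wsum
  dd[wsum == 0] <- NA; se[wsum == 0] <- NA
  structure(list(delta_d = dd, se = se, profiles = NULL,
                 n_pairs = NULL, tau_short = matrices[[1]]$tau_short,
                 Rcut_range = matrices[[1]]$Rcut_range),
            class = "interaction_matrix")
}

#' Names of the glycolysis-pathway enzymes
#'
#' The ten glycolytic enzymes analysed as their own interaction group.
#' @return Character vector of enzyme tags.
#' @export
glycolytic_enzymes <- function() {
  c("HPRK", "PYK", "TPIA", "GAPA", "PFKA", "FBA", "ENO", "PGI", "PGM",
    "PGK")
}
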