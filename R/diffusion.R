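#' Windowed mean-square displacement
#'
#' Computes the time-averaged MSD over sliding windows: origins advance in
#' steps of `dt_i` from the start of the trajectory up to `tend - tau_max`
#' (the same origin set for every lag), and displacements are averaged over
#' origins and over the selected particles.  Multi-bead bodies are tracked
#' by their center of mass when `com_by_molecule = TRUE`.
#'
#' @param traj An unwrapped [trajectory()] (wrapped input is an error --
#'   displacements across box jumps are unphysical).
#' @param selection Particle indices or species name(s); default all.
#' @param tau_max Largest window size, ps (must be < trajectory span).
#' @param dt_i Window-origin interval, ps (default: one frame spacing).
#' @param com_by_molecule Track molecule centers of mass instead of
#'   individual particles.
#' @return An object of class `"msd_curve"`: data.frame with `tau` (ps) and
#'   `msd` (A^2), with the per-particle MSD matrix, window count and
#'   parameters as attributes.
#' @export
compute_msd <- function(traj, selection = NULL, tau_max = NULL,
                        dt_i = NULL, com_by_molecule = FALSE) {
  if (traj$wrapped)
    stop("trajectory is wrapped; unwrap_trajectory() it first")
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  dt_frame <- traj$times[2] - traj$times[1]
  if (max(abs(diff(traj$times) - dt_frame)) > 1e-6 * dt_frame)
    stop("MSD windowing requires uniformly spaced frames")
  tend <- traj$times[nf] - traj$times[1]
  if (is.null(tau_max)) tau_max <- tend / 2
  if (tau_max >= tend) stop("tau_max must be smaller than the trajectory ",
                            "span (", tend, " ps)")
  if (is.null(dt_i)) dt_i <- dt_frame
  ostride <- max(1L, as.integer(round(dt_i / dt_frame)))
  idx <- resolve_selection(traj, selection)
  co <- traj$coords[, idx, , drop = FALSE]
  labels <- idx
  if (com_by_molecule) {
    mol <- traj$molecule_index[idx]
    um <- unique(mol)
    com <- array(0, c(nf, length(um), 3))
    for (k in seq_along(um)) {
      sel <- which(mol == um[k])
      com[, k, ] <- apply(co[, sel, , drop = FALSE], c(1, 3), mean)
    }
    co <- com
    labels <- um
  }
  ntau <- as.integer(floor(tau_max / dt_frame))
  taus <- seq_len(ntau)                    # in frames; tau = 0 is trivial
  max_origin <- nf - 1L - ntau
  per <- cpp_msd(co, taus, ostride, max_origin)
  msd <- rowMeans(per)
  out <- data.frame(tau = c(0, taus * dt_frame), msd = c(0, msd))
  structure(out,
            per_particle = rbind(0, per),
            particles = labels,
            n_windows = max_origin %/% ostride + 1L,
            params = list(tau_max = tau_max, dt_i = ostride * dt_frame,
                          tend = tend),
            class = c("msd_curve", "data.frame"))
}

resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(n_particles(traj)))
  if (is.character(selection)) {
    keep <- traj$table$name[traj$species_index] %in% selection
    if (!any(keep)) stop("selection matches no particles")
    return(which(keep))
  }
  if (inherits(selection, "atom_group_selection")) return(selection$indices)
  as.integer(selection)
}

#' @export
print.msd_curve <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "MSD curve: %d lags up to %.4g ps, %d window origins (dt_i = %.4g ps)\n",
    nrow(x) - 1, max(x$tau), attr(x, "n_windows"), p$dt_i))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$tau, x$msd, type = "l", xlab = "tau (ps)",
                 ylab = "MSD (A^2)", ...)
  invisible(x)
}

#' Translational diffusion constant from an MSD curve
#'
#' Least-squares line through the selected portion of the MSD curve;
#' `D_tr = slope / 6` (Einstein relation in three dimensions).  By default
#' only the last 80% of the curve is used, which suppresses the short-lag
#' portion where windowed statistics are most correlated and any ballistic
#' or cage contamination lives; `fit_fraction = 1` uses the entire curve
#' (the variant used when correlating diffusion with local crowding).
#'
#' @param curve An [compute_msd()] result.
#' @param fit_fraction Fraction of the curve (from the end) to fit.
#' @param d0 Reference dilute diffusion constant (A^2/ps), e.g. from a
#'   hydrodynamic calculation or [stokes_einstein_D()]; enables the
#'   `ratio` field.
#' @param dimensions 3 for bulk diffusion (slope/6), 2 for surface
#'   diffusion (slope/4).
#' @return Object of class `"diffusion_fit"` with `D_tr` (A^2/ps), fit
#'   diagnostics, optional per-copy values, `D0` and `ratio`.
#' @export
fit_dtr <- function(curve, fit_fraction = 0.8, d0 = NULL, dimensions = 3) {
  stopifnot(fit_fraction > 0, fit_fraction <= 1, dimensions %in% c(2, 3))
  n <- nrow(curve)
  from <- max(1L, n - as.integer(ceiling(fit_fraction * (n - 1))))
  sel <- from:n
  if (length(sel) < 10)
    stop("need >= 10 MSD points in the fit range")
  fac <- 2 * dimensions
  fit <- stats::lm(msd ~ tau, data = curve[sel, ])
  slope <- unname(coef(fit)[2])
  D <- slope / fac
  warn <- slope < 0
  per <- attr(curve, "per_particle")
  per_copy <- NULL
  if (!is.null(per) && ncol(per) > 1) {
    per_copy <- apply(per[sel, , drop = FALSE], 2, function(m)
      unname(coef(stats::lm(m ~ curve$tau[sel]))[2]) / fac)
    names(per_copy) <- attr(curve, "particles")
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(D_tr = D, fit_window = fit_fraction, r_squared = r2,
                 negative_slope = warn, per_copy = per_copy,
                 D0 = d0, ratio = if (!is.null(d0)) D / d0 else NULL,
                 dimensions = dimensions),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("D_tr = %.6g A^2/ps (last %d%% fit, R^2 = %.4f%s)\n",
              x$D_tr, round(100 * x$fit_window), x$r_squared,
              if (x$negative_slope) ", NEGATIVE SLOPE" else ""))
  if (!is.null(x$ratio))
    cat(sprintf("D0 = %.6g A^2/ps, D_tr/D0 = %.4f\n", x$D0, x$ratio))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) c(D_tr = object$D_tr)

#' Size-scaling fits of diffusion constants
#'
#' Fits the standard one-parameter scaling laws of crowded-solution
#' diffusion: `D = A / Rs^2` (crowded absolute diffusion vs Stokes radius),
#' `D/D0 = B / Rs` (crowding slow-down relative to dilute), a free-exponent
#' power law `Rs = c * Mw^b` (Stokes radius vs molecular weight), or an
#' ordinary linear law (used for normalized diffusion vs normalized
#' coordination number).  One-parameter laws are fitted through the origin
#' in the transformed variable, matching their printed single-coefficient
#' forms.
#'
#' @param x Stokes radii (A) for the first two models; molecular weights
#'   (Da) for `powerlaw_Rs_of_Mw`; the abscissa for `linear_norm`.
#' @param y Diffusion constants or ratios; Stokes radii for the power law.
#' @param model Which functional form to fit.
#' @return Object of class `"scaling_fit"` with `coefficients`,
#'   `residuals`, and the Pearson correlation of observed vs fitted.
#' @export
fit_size_scaling <- function(x, y, model = c("A_over_Rs2", "B_over_Rs",
                                             "powerlaw_Rs_of_Mw",
                                             "linear_norm")) {
  model <- match.arg(model)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (model %in% c("A_over_Rs2", "B_over_Rs") && any(x <= 0))
    stop("Stokes radii must be > 0")
  cf <- switch(model,
    A_over_Rs2 = {
      z <- 1 / x^2
      c(A = sum(y * z) / sum(z * z))
    },
    B_over_Rs = {
      if (length(x) < 2) stop("need >= 2 species")
      z <- 1 / x
      c(B = sum(y * z) / sum(z * z))
    },
    powerlaw_Rs_of_Mw = {
      if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive ",
                                           "weights and radii")
      f <- stats::lm(log(y) ~ log(x))
      c(c = unname(exp(coef(f)[1])), b = unname(coef(f)[2]))
    },
    linear_norm = {
      f <- stats::lm(y ~ x)
      c(n = unname(coef(f)[1]), m = unname(coef(f)[2]))
    })
  fitted <- switch(model,
    A_over_Rs2 = cf[["A"]] / x^2,
    B_over_Rs = cf[["B"]] / x,
    powerlaw_Rs_of_Mw = cf[["c"]] * x^cf[["b"]],
    linear_norm = cf[["n"]] + cf[["m"]] * x)
  structure(list(model = model, coefficients = cf,
                 residuals = y - fitted, x = x, y = y, fitted = fitted,
                 correlation = if (length(x) > 2)
                   stats::cor(y, fitted) else NA_real_),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit [%s]: %s\n", x$model,
              paste(sprintf("%s = %.6g", names(x$coefficients),
                            x$coefficients), collapse = ", ")))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) object$coefficients

#' Per-species diffusion summary of a crowded run
#'
#' Convenience wrapper: per-species MSD and last-80% diffusion fit, dilute
#' reference `D0` (user-supplied per species, else Stokes-Einstein from the
#' radius, flagged in the output), and the `D_tr/D0` ratio.
#'
#' @param traj Unwrapped [trajectory()] of a crowded run.
#' @param tau_max,dt_i Passed to [compute_msd()].
#' @param d0 Optional named vector of dilute diffusion constants per
#'   species; defaults to Stokes-Einstein from the table radii.
#' @param fit_fraction Passed to [fit_dtr()].
#' @return data.frame with one row per species: `name`, `stokes_radius`,
#'   `D_tr`, `D0`, `ratio`, `d0_source`.
#' @export
species_diffusion <- function(traj, tau_max = NULL, dt_i = NULL, d0 = NULL,
                              fit_fraction = 0.8) {
  tab <- traj$table
  rows <- lapply(seq_len(nrow(tab)), function(s) {
    idx <- which(traj$species_index == s)
    if (!length(idx)) return(NULL)
    cur <- compute_msd(traj, idx, tau_max = tau_max, dt_i = dt_i)
    d0s <- if (!is.null(d0) && tab$name[s] %in% names(d0))
      d0[[tab$name[s]]] else stokes_einstein_D(tab$stokes_radius[s])
    f <- fit_dtr(cur, fit_fraction, d0 = d0s)
    data.frame(name = tab$name[s], stokes_radius = tab$stokes_radius[s],
               D_tr = f$D_tr, D0 = d0s, ratio = f$ratio,
               d0_source = if (!is.null(d0) && tab$name[s] %in% names(d0))
                 "table" else "stokes_einstein",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify metabolite surface diffusion
#'
#' A metabolite frame is "interacting" when its position lies within the
#' per-species cutoff of the nearest macromolecule bead; a frame belongs to
#' a surface segment when the metabolite has been bound to the SAME
#' macromolecule continuously for more than `min_residence` both before and
#' after that frame.  Surface-frame MSD slopes are divided by 4
#' (two-dimensional diffusion), bulk slopes by 6.
#'
#' @param met_traj Unwrapped metabolite [trajectory()].
#' @param macro_traj Macromolecule trajectory sharing times and box.
#' @param cutoffs Named per-species interaction cutoffs in A (or a single
#'   number), e.g. 10 for large cofactors, 8 for small metabolites.
#' @param min_residence Minimum continuous residence, ps (default 5000).
#' @param tau_max MSD window for the per-population diffusion fits, ps.
#' @return List of class `"surface_diffusion"`: per-metabolite logical
#'   matrix of surface frames, residency segments, `D_surface`, `D_bulk`.
#' @export
classify_surface_diffusion <- function(met_traj, macro_traj, cutoffs = 8,
                                       min_residence = 5000,
                                       tau_max = NULL) {
  if (length(met_traj$times) != length(macro_traj$times) ||
      max(abs(met_traj$times - macro_traj$times)) > 1e-9)
    stop("metabolite and macromolecule trajectories must share times")
  L <- box_L(met_traj$box)
  if (abs(L - box_L(macro_traj$box)) > 1e-9)
    stop("trajectories must share the box")
  nf <- n_frames(met_traj)
  nm <- n_particles(met_traj)
  met_names <- met_traj$table$name[met_traj$species_index]
  cut <- if (is.null(names(cutoffs))) rep(cutoffs[1], nm)
         else {
           cc <- cutoffs[met_names]
           if (anyNA(cc)) stop("cutoffs missing for species: ",
                               paste(unique(met_names[is.na(cc)]),
                                     collapse = ", "))
           as.numeric(cc)
         }
  radii <- macro_traj$table$stokes_radius[macro_traj$species_index]
  bound_id <- matrix(NA_integer_, nf, nm)
  for (f in seq_len(nf)) {
    near <- cpp_nearest_surface(frame_coords(met_traj, f),
                                frame_coords(macro_traj, f),
                                rep(0, length(radii)), L)
    ok <- near$dist < cut
    bound_id[f, ok] <- macro_traj$molecule_index[near$index[ok]]
  }
  dtf <- met_traj$times[2] - met_traj$times[1]
  need <- as.integer(ceiling(min_residence / dtf))
  surface <- matrix(FALSE, nf, nm)
  segments <- list()
  for (m in seq_len(nm)) {
    r <- rle(ifelse(is.na(bound_id[, m]), -1L, bound_id[, m]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] < 0) next
      dur <- (r$lengths[k] - 1L) * dtf
      if (dur > min_residence)     # residency segment: continuous binding
        segments[[length(segments) + 1]] <-
          data.frame(metabolite = m, partner = r$values[k],
                     from = met_traj$times[starts[k]],
                     to = met_traj$times[ends[k]])
      # surface frames: > min_residence of same-partner binding BOTH before
      # and after the frame
      lo <- starts[k] + need; hi <- ends[k] - need
      if (lo <= hi) surface[lo:hi, m] <- TRUE
    }
  }
  segs <- if (length(segments)) do.call(rbind, segments)
          else data.frame(metabolite = integer(), partner = integer(),
                          from = numeric(), to = numeric())
  pop_D <- function(mask, dims) {
    # MSD restricted to windows fully inside the population mask
    vals <- c()
    for (m in seq_len(nm)) {
      runs <- rle(mask[, m])
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (k in seq_along(runs$values)) {
        if (!runs$values[k] || runs$lengths[k] < 12) next
        co <- met_traj$coords[starts[k]:ends[k], m, , drop = FALSE]
        sub <- trajectory(met_traj$times[starts[k]:ends[k]], co,
                          box = met_traj$box, wrapped = FALSE)
        tm <- (runs$lengths[k] - 1) * dtf / 2
        cur <- compute_msd(sub, tau_max = if (is.null(tau_max)) tm
                                          else min(tau_max, tm))
        f <- try(fit_dtr(cur, dimensions = dims), silent = TRUE)
        if (!inherits(f, "try-error"))
          vals <- c(vals, setNames(f$D_tr, runs$lengths[k]))
      }
    }
    if (!length(vals)) return(NA_real_)
    # weight segment estimates by their length
    sum(vals * as.numeric(names(vals))) / sum(as.numeric(names(vals)))
  }
  structure(list(surface = surface, segments = segs,
                 D_surface = pop_D(surface, 2),
                 D_bulk = pop_D(is.na(bound_id), 3),
                 interacting_fraction = mean(!is.na(bound_id))),
            class = "surface_diffusion")
}

#' @export
print.surface_diffusion <- function(x, ...) {
  cat(sprintf(paste0("Surface diffusion: %d segments, D_surface = %.4g, ",
                     "D_bulk = %.4g A^2/ps\n"),
              nrow(x$segments), x$D_surface, x$D_bulk))
  cat(sprintf("Interacting fraction: %.1f%%\n",
              100 * x$interacting_fraction))
  invisible(x)
}
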