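#' Best-fit (least-RMSD) rotation between two coordinate sets
#'
#' Kabsch-type construction via singular value decomposition, with a
#' reflection guard so the result is a proper rotation (det = +1).
#' Both coordinate sets are centered before superposition.
#'
#' @param P,Q m x 3 coordinate matrices (moving and reference).
#' @return 3 x 3 rotation matrix `R` minimizing `|| (P - cP) R' - (Q - cQ) ||`,
#'   i.e. rotated coordinates are `sweep(P, 2, colMeans(P)) %*% t(R)`.
#' @export
kabsch_rotation <- function(P, Q) {
  P <- rbind(P); Q <- rbind(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("need at least 3 points for a unique superposition")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)        # 3x3 covariance
  s <- svd(H)
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2)
    stop("degenerate (collinear) atom group: superposition is not unique")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R
}

# orientation matrices of an atom-group trajectory against a reference
orientations_from_beads <- function(traj, reference, selection = NULL) {
  idx <- resolve_selection(traj, selection)
  ref <- rbind(reference)
  if (nrow(ref) != length(idx))
    stop("reference and selection differ in atom count")
  nf <- n_frames(traj)
  rot <- array(0, c(nf, 3, 3, 1))
  for (f in seq_len(nf)) {
    co <- matrix(traj$coords[f, idx, ], ncol = 3)
    rot[f, , , 1] <- kabsch_rotation(ref, co) # rotation taking ref -> frame
  }
  structure(list(times = traj$times, rotations = rot, n_copies = 1),
            class = "orientation_track")
}

as_orientation_track <- function(x, reference = NULL, selection = NULL) {
  if (inherits(x, "orientation_track")) return(x)
  if (inherits(x, "bd_traj")) {
    if (!is.null(x$orientations)) {
      rot <- x$orientations
      if (length(dim(rot)) == 3) dim(rot) <- c(dim(rot), 1)
      return(structure(list(times = x$times, rotations = rot,
                            n_copies = dim(rot)[4]),
                       class = "orientation_track"))
    }
    if (is.null(reference))
      stop("atom-group trajectory needs a reference structure for ",
           "best-fit superposition")
    return(orientations_from_beads(x, reference, selection))
  }
  stop("cannot interpret input as an orientation track")
}

#' Rotational correlation function
#'
#' The window-averaged first-rank orientation autocorrelation: the three
#' body-frame unit vectors (columns of the best-fit rotation operator) are
#' correlated between window start and lag tau, averaged over the three
#' vectors, window origins and copies.  For free isotropic rotational
#' diffusion the curve decays as `exp(-2 D_rot tau)`; the curve equals 1
#' at tau = 0 by construction.
#'
#' @param x An `orientation_track` (from [gen_rigid_rotor()]) or a
#'   [trajectory()] whose orientations are computed by least-RMSD
#'   superposition against `reference`.
#' @param tau_max Largest lag, ps.
#' @param dt_i Window-origin interval, ps (default one frame).
#' @param reference,selection Used when `x` is an atom-group trajectory.
#' @return Object of class `"rot_corr"`: data.frame with `tau`, `theta`.
#' @export
rotational_correlation <- function(x, tau_max = NULL, dt_i = NULL,
                                   reference = NULL, selection = NULL) {
  tr <- as_orientation_track(x, reference, selection)
  nf <- length(tr$times)
  dtf <- tr$times[2] - tr$times[1]
  tend <- tr$times[nf] - tr$times[1]
  if (is.null(tau_max)) tau_max <- tend / 2
  if (tau_max >= tend) stop("tau_max must be below the track span")
  ostride <- if (is.null(dt_i)) 1L else max(1L, as.integer(round(dt_i /
                                                                 dtf)))
  ntau <- as.integer(floor(tau_max / dtf))
  max_origin <- nf - 1L - ntau
  origins <- seq(1L, 1L + max_origin, by = ostride)
  theta <- numeric(ntau)
  for (t in seq_len(ntau)) {
    acc <- 0
    for (c in seq_len(tr$n_copies)) {
      for (o in origins) {
        R0 <- tr$rotations[o, , , c]
        R1 <- tr$rotations[o + t, , , c]
        # mean over the three body axes of e_j(t0+tau) . e_j(t0)
        acc <- acc + sum(R1 * R0) / 3
      }
    }
    theta[t] <- acc / (length(origins) * tr$n_copies)
  }
  structure(data.frame(tau = c(0, seq_len(ntau) * dtf),
                       theta = c(1, theta)),
            params = list(tau_max = tau_max, dt_i = ostride * dtf),
            class = c("rot_corr", "data.frame"))
}

#' @export
plot.rot_corr <- function(x, ...) {
  graphics::plot(x$tau, x$theta, type = "l", xlab = "tau (ps)",
                 ylab = "theta(tau)", ylim = c(min(x$theta, 0), 1), ...)
  invisible(x)
}

#' Rotational relaxation time and diffusion constant
#'
#' Single-exponential fit `theta(tau) = exp(-tau/tau_rel)` by nonlinear
#' least squares restricted to the decaying portion `theta in [0.1, 1]`;
#' the rotational diffusion constant follows as `D_rot = 1/(2 tau_rel)`.
#' A curve that never decays below 0.9 within range cannot be fitted and is
#' returned flagged, with an infinite relaxation time.
#'
#' @param curve A [rotational_correlation()] result.
#' @return Object of class `"rotation_fit"`: `tau_rel` (ps), `D_rot`
#'   (1/ps), `fitted` flag.
#' @export
fit_rotational_relaxation <- function(curve) {
  sel <- curve$theta >= 0.1
  x <- curve$tau[sel]; y <- curve$theta[sel]
  if (min(curve$theta) > 0.9 || sum(y < 1) < 3) {
    return(structure(list(tau_rel = Inf, D_rot = 0, fitted = FALSE),
                     class = "rotation_fit"))
  }
  # log-linear start value, then proper NLS on the linear scale
  pos <- y > 0
  start <- -1 / unname(coef(stats::lm(log(y[pos]) ~ x[pos] - 1))[1])
  if (!is.finite(start) || start <= 0) start <- max(x) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-x / tau), start = list(tau = start),
                      lower = 1e-12, upper = Inf),
    error = function(e) NULL)
  tau_rel <- if (is.null(fit)) start else unname(coef(fit)[["tau"]])
  structure(list(tau_rel = tau_rel, D_rot = 1 / (2 * tau_rel),
                 fitted = TRUE),
            class = "rotation_fit")
}

#' @export
print.rotation_fit <- function(x, ...) {
  if (!x$fitted)
    cat("Rotational relaxation: no decay within range (tau_rel = Inf)\n")
  else
    cat(sprintf("tau_rel = %.6g ps, D_rot = %.6g /ps\n", x$tau_rel,
                x$D_rot))
  invisible(x)
}

#' Mean angular velocity over the observation window
#'
#' The inner products of the three rotated body-frame unit vectors between
#' window start and window end (`tau_max`) are averaged over vectors and
#' origins; the mean rotation angle is `arccos` of that average, reported
#' in degrees.  By default the value is the angle accumulated per
#' observation window (as the correlation machinery defines it); per-ns
#' units are available.
#'
#' @inheritParams rotational_correlation
#' @param units `"per_window"` (degrees per `tau_max` window) or
#'   `"per_ns"` (degrees per nanosecond).
#' @return Mean angular velocity (degrees), with attribute `tau_max`.
#' @export
mean_angular_velocity <- function(x, tau_max = NULL, dt_i = NULL,
                                  reference = NULL, selection = NULL,
                                  units = c("per_window", "per_ns")) {
  units <- match.arg(units)
  tr <- as_orientation_track(x, reference, selection)
  nf <- length(tr$times)
  dtf <- tr$times[2] - tr$times[1]
  tend <- tr$times[nf] - tr$times[1]
  if (is.null(tau_max)) tau_max <- tend / 2
  ntau <- as.integer(round(tau_max / dtf))
  if (ntau < 1 || ntau > nf - 1) stop("tau_max outside the track span")
  ostride <- if (is.null(dt_i)) 1L else max(1L, as.integer(round(dt_i /
                                                                 dtf)))
  origins <- seq(1L, nf - ntau, by = ostride)
  acc <- 0
  for (c in seq_len(tr$n_copies))
    for (o in origins)
      acc <- acc + sum(tr$rotations[o + ntau, , , c] *
                       tr$rotations[o, , , c]) / 3
  de <- acc / (length(origins) * tr$n_copies)
  if (de > 1 || de < -1) {
    if (abs(de) > 1 + 1e-8)
      warning("mean inner product outside [-1, 1]; clamped")
    de <- max(-1, min(1, de))
  }
  ang <- 180 / pi * acos(de)
  out <- if (units == "per_ns") ang / (ntau * dtf / 1000) else ang
  structure(out, tau_max = ntau * dtf, units = units)
}
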