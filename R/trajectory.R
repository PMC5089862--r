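#' Particle trajectories
#'
#' A trajectory holds frames x particles x 3 coordinates (Angstrom), strictly
#' increasing frame times (ps), a per-particle species assignment into a
#' [species_table()], the periodic box, and a `wrapped` flag stating whether
#' coordinates lie in `[0, L)`.  Rigid-body analyses may additionally carry a
#' per-frame orientation track (see [gen_rigid_rotor()]).
#'
#' @param times Numeric vector of frame times in ps, strictly increasing.
#' @param coords Numeric array `c(n_frames, n_particles, 3)`.
#' @param species_index Integer vector mapping each particle to a row of
#'   `table` (defaults to species 1 for all).
#' @param table A [species_table()] (defaults to a single generic species).
#' @param box A [sim_box()].
#' @param wrapped Logical: are coordinates wrapped into the primary box?
#' @param molecule_index Optional integer vector grouping particles into
#'   molecules (defaults to one molecule per particle); used by bead-cluster
#'   analyses.
#' @param orientations Optional orientation track: array
#'   `c(n_frames, 3, 3)` or `c(n_frames, 3, 3, n_bodies)` of rotation
#'   matrices.
#' @return An object of class `"bd_traj"`.
#' @export
trajectory <- function(times, coords, species_index = NULL, table = NULL,
                       box = NULL, wrapped = FALSE, molecule_index = NULL,
                       orientations = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]; np <- dim(coords)[2]
  if (nf < 1) stop("trajectory must have at least one frame")
  stopifnot(length(times) == nf)
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(table))
    table <- species_table("particle", 10, np)
  if (is.null(species_index)) species_index <- rep(1L, np)
  stopifnot(length(species_index) == np,
            all(species_index >= 1), all(species_index <= nrow(table)))
  if (is.null(molecule_index)) molecule_index <- seq_len(np)
  stopifnot(length(molecule_index) == np)
  if (is.null(box)) box <- sim_box(max(1, max(abs(coords)) * 2), FALSE)
  L <- box_L(box)
  if (isTRUE(wrapped) && L > 0 &&
      (min(coords) < 0 || max(coords) >= L))
    stop("wrapped trajectory has coordinates outside [0, edge_length)")
  structure(list(times = as.numeric(times), coords = coords,
                 species_index = as.integer(species_index), table = table,
                 box = box, wrapped = isTRUE(wrapped),
                 molecule_index = as.integer(molecule_index),
                 orientations = orientations),
            class = "bd_traj")
}

#' @export
print.bd_traj <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d particles, t = %.4g..%.4g ps, %s%s\n",
    n_frames(x), n_particles(x), x$times[1], x$times[n_frames(x)],
    if (x$wrapped) "wrapped" else "unwrapped",
    if (!is.null(x$orientations)) ", with orientation track" else ""))
  print(x$box)
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `bd_traj`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

# n x 3 coordinate matrix of one frame
frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

#' Unwrap a periodic trajectory into continuous particle paths
#'
#' Removes box jumps so displacements are physical (required before any
#' mean-square-displacement analysis).  The per-frame displacement of every
#' particle must be below half the box edge; larger apparent jumps cannot be
#' disambiguated and raise an error (the frame rate is too low).
#'
#' @param traj A wrapped [trajectory()].
#' @return The unwrapped trajectory (`wrapped = FALSE`); re-wrapping with
#'   [wrap_trajectory()] reproduces the input modulo the box length.
#' @export
unwrap_trajectory <- function(traj) {
  if (!traj$wrapped) stop("trajectory is not wrapped")
  L <- box_L(traj$box)
  if (L <= 0) { traj$wrapped <- FALSE; return(traj) }
  co <- traj$coords
  nf <- dim(co)[1]
  if (nf > 1) {
    d <- co[-1, , , drop = FALSE] - co[-nf, , , drop = FALSE]
    jump <- -L * round(d / L)
    # minimum-image steps approaching the half box cannot be assigned
    # reliably; flag anything at or beyond 40% of the edge
    if (any(abs(d + jump) >= 0.4 * L))
      stop("ambiguous unwrap: per-frame displacement approaches ",
           "edge_length/2 (frame rate too low)")
    cj <- apply(jump, c(2, 3), cumsum)
    dim(cj) <- dim(jump)  # apply drops the frame dim when nf == 2
    co[-1, , ] <- co[-1, , , drop = FALSE] + cj
  }
  traj$coords <- co
  traj$wrapped <- FALSE
  traj
}

#' @rdname unwrap_trajectory
#' @export
wrap_trajectory <- function(traj) {
  L <- box_L(traj$box)
  if (L > 0) {
    w <- traj$coords %% L
    w[w >= L] <- 0
    traj$coords <- w
  }
  traj$wrapped <- TRUE
  traj
}
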