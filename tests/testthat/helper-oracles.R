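# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's compiled code paths.

# minimum-image displacement, plain R
mi_r <- function(d, L) if (L > 0) d - L * round(d / L) else d

# all-pairs half-harmonic energy + forces, plain R (oracle for cpp_forces)
forces_oracle_hh <- function(coords, radii, L, k = 10, delta = 1) {
  n <- nrow(coords)
  E <- 0
  F <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dv <- mi_r(coords[i, ] - coords[j, ], L)
    r <- sqrt(sum(dv^2))
    rc <- radii[i] + radii[j] + delta
    if (r < rc) {
      x <- r - radii[i] - radii[j] - delta
      E <- E + 0.5 * k * x^2
      fmag <- -k * x
      F[i, ] <- F[i, ] + fmag * dv / r
      F[j, ] <- F[j, ] - fmag * dv / r
    }
  }
  list(energy = E, forces = F)
}

# windowed MSD by explicit double loop (oracle for compute_msd)
msd_oracle <- function(coords, taus, ostride, max_origin) {
  nf <- dim(coords)[1]; np <- dim(coords)[2]
  origins <- seq(1, 1 + max_origin, by = ostride)
  out <- matrix(0, length(taus), np)
  for (t in seq_along(taus)) for (p in seq_len(np)) {
    acc <- 0
    for (o in origins) {
      d <- coords[o + taus[t], p, ] - coords[o, p, ]
      acc <- acc + sum(d^2)
    }
    out[t, p] <- acc / length(origins)
  }
  out
}

# quaternion random-walk rotor (independent of the package's rotation-vector
# generator); returns mean first-rank autocorrelation at the given lags
quat_rotor_autocorr <- function(Drot, dt, steps, lags, n_copies = 20) {
  qmul <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(
      a[3] * b[4] - a[4] * b[3],
      a[4] * b[2] - a[2] * b[4],
      a[2] * b[3] - a[3] * b[2]))
  qrot <- function(q, v) {
    # rotate v by unit quaternion q
    t2 <- 2 * c(q[3] * v[3] - q[4] * v[2],
                q[4] * v[1] - q[2] * v[3],
                q[2] * v[2] - q[3] * v[1])
    v + q[1] * t2 + c(q[3] * t2[3] - q[4] * t2[2],
                      q[4] * t2[1] - q[2] * t2[3],
                      q[2] * t2[2] - q[3] * t2[1])
  }
  acc <- matrix(0, length(lags), n_copies)
  for (cc in seq_len(n_copies)) {
    q <- c(1, 0, 0, 0)
    es <- matrix(0, steps + 1, 3)
    es[1, ] <- c(1, 0, 0)
    for (s in seq_len(steps)) {
      w <- rnorm(3, sd = sqrt(2 * Drot * dt))
      th <- sqrt(sum(w^2))
      dq <- c(cos(th / 2), sin(th / 2) * w / max(th, 1e-300))
      q <- qmul(dq, q)
      q <- q / sqrt(sum(q^2))
      es[s + 1, ] <- qrot(q, c(1, 0, 0))
    }
    for (t in seq_along(lags)) {
      tau <- lags[t]
      o <- seq_len(steps + 1 - tau)
      acc[t, cc] <- mean(rowSums(es[o + tau, , drop = FALSE] *
                                   es[o, , drop = FALSE]))
    }
  }
  rowMeans(acc)
}

# rotation matrix about the z axis
rot_z <- function(phi) {
  matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1), 3, 3)
}

# build a bd_traj directly from an array (test convenience)
make_traj <- function(coords, times = NULL, box = NULL, wrapped = FALSE,
                      table = NULL, species_index = NULL,
                      molecule_index = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  times <- times %||% (seq_len(dim(coords)[1]) - 1)
  trajectory(times, coords, species_index, table, box, wrapped,
             molecule_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
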