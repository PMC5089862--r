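test_that("windowed MSD matches closed forms and the double-loop oracle", {
  # static particle: identically zero
  co <- array(5, c(50, 1, 3))
  tr <- make_traj(co, times = (0:49) * 10)
  m <- compute_msd(tr, tau_max = 200)
  expect_true(all(m$msd == 0))

  # ballistic motion x = v t: msd(tau) = v^2 tau^2 exactly
  v <- 0.3
  co <- array(0, c(60, 1, 3)); co[, 1, 1] <- v * (0:59) * 10
  m <- compute_msd(make_traj(co, times = (0:59) * 10), tau_max = 250)
  expect_equal(m$msd, v^2 * m$tau^2)

  # brute-force oracle equality on 5 particles x 100 frames
  set.seed(6)
  co <- apply(array(rnorm(100 * 5 * 3), c(100, 5, 3)), c(2, 3), cumsum)
  tr <- make_traj(co, times = (0:99) * 2)
  m <- compute_msd(tr, tau_max = 80, dt_i = 6)
  taus <- seq_len(40)
  ora <- msd_oracle(co, taus, ostride = 3, max_origin = 100 - 1 - 40)
  expect_equal(attr(m, "per_particle")[-1, ], ora)
  expect_equal(m$msd[-1], rowMeans(ora))

  # wrapped input and oversized windows are rejected
  wtr <- make_traj(co %% 20, box = sim_box(20), wrapped = TRUE)
  expect_error(compute_msd(wtr), "unwrap")
  expect_error(compute_msd(tr, tau_max = 1000), "tau_max")
})

test_that("MSD estimates are invariant under translation and re-indexing", {
  set.seed(7)
  co <- apply(array(rnorm(80 * 4 * 3), c(80, 4, 3)), c(2, 3), cumsum)
  tr <- make_traj(co, times = (0:79) * 5)
  m1 <- compute_msd(tr, tau_max = 100)
  shifted <- make_traj(co + 123.4, times = (0:79) * 5)
  m2 <- compute_msd(shifted, tau_max = 100)
  expect_equal(m1$msd, m2$msd)
  perm <- c(3, 1, 4, 2)
  m3 <- compute_msd(make_traj(co[, perm, , drop = FALSE],
                              times = (0:79) * 5), tau_max = 100)
  expect_equal(m1$msd, m3$msd)
})

test_that("diffusion fits recover slopes, ratios, and resist contamination", {
  # exact line msd = 6 D tau
  tau <- seq(0, 1000, by = 10)
  curve <- structure(data.frame(tau = tau, msd = 6 * 0.05 * tau),
                     class = c("msd_curve", "data.frame"))
  f <- fit_dtr(curve)
  expect_equal(f$D_tr, 0.05, tolerance = 1e-12)
  f2 <- fit_dtr(curve, d0 = 0.1)
  expect_equal(f2$ratio, 0.5, tolerance = 1e-12)

  # walkers with known D: recovery within 5%
  tr <- gen_brownian_walkers(200, 0.1, 10, 1000, seed = 3)
  fw <- fit_dtr(compute_msd(tr, tau_max = 1000))
  expect_lt(abs(fw$D_tr - 0.1) / 0.1, 0.05)
  expect_length(fw$per_copy, 200)

  # ballistic contamination at small tau: last-80% fit is closer to the
  # asymptotic slope than the full-range fit
  msd <- 6 * 0.05 * tau + 40 * (1 - exp(-tau / 30))
  curve2 <- structure(data.frame(tau = tau, msd = msd),
                      class = c("msd_curve", "data.frame"))
  err80 <- abs(fit_dtr(curve2, 0.8)$D_tr - 0.05)
  errfull <- abs(fit_dtr(curve2, 1.0)$D_tr - 0.05)
  expect_lt(err80, errfull)

  # negative slope is flagged, not hidden
  curve3 <- structure(data.frame(tau = tau, msd = 100 - 0.01 * tau),
                      class = c("msd_curve", "data.frame"))
  expect_true(fit_dtr(curve3)$negative_slope)
})

test_that("size-scaling laws are recovered exactly from noiseless data", {
  Rs <- c(15.8, 22, 30, 40, 55, 80, 105)
  # D = 341 / Rs^2
  f1 <- fit_size_scaling(Rs, 341 / Rs^2, "A_over_Rs2")
  expect_equal(unname(coef(f1)[["A"]]), 341, tolerance = 1e-12)
  # D/D0 = 5.6 / Rs
  f2 <- fit_size_scaling(Rs, 5.6 / Rs, "B_over_Rs")
  expect_equal(unname(coef(f2)[["B"]]), 5.6, tolerance = 1e-12)
  # free-exponent power law Rs = c Mw^b
  Mw <- c(9e3, 2e4, 4.5e4, 2.3e5, 2e5, 8e5, 2.7e6)
  f3 <- fit_size_scaling(Mw, 2.54 * Mw^0.286, "powerlaw_Rs_of_Mw")
  expect_equal(unname(coef(f3)[["b"]]), 0.286, tolerance = 1e-9)
  expect_equal(unname(coef(f3)[["c"]]), 2.54, tolerance = 1e-6)
  expect_error(fit_size_scaling(c(0, 10), c(1, 2), "B_over_Rs"), "> 0")

  # linear law with noise: slope recovered within its own 3 SE
  set.seed(11)
  x <- runif(200, 0.5, 1.5)
  y <- 1.8 - 0.9 * x + rnorm(200, sd = 0.1)
  f4 <- fit_size_scaling(x, y, "linear_norm")
  lmref <- stats::lm(y ~ x)
  se <- summary(lmref)$coefficients[2, 2]
  expect_lt(abs(coef(f4)[["m"]] - (-0.9)), 3 * se)
})

test_that("surface-diffusion classifier applies the residence rule", {
  # one static macromolecule bead at the origin of a large box
  L <- 200
  nf <- 101
  mac <- make_traj(array(rep(c(100, 100, 100), each = nf), c(nf, 1, 3)),
                   times = (0:100) * 500, box = sim_box(L),
                   molecule_index = 1L)
  far <- array(rep(c(30, 30, 30), each = nf), c(nf, 1, 3))
  met_far <- make_traj(far, times = (0:100) * 500, box = sim_box(L))
  out <- classify_surface_diffusion(met_far, mac, cutoffs = 8)
  expect_equal(nrow(out$segments), 0)
  expect_equal(out$interacting_fraction, 0)

  # bound for 6 ns (12 frames at 500 ps), then released: one residency
  # segment under the 5 ns rule
  pos <- array(rep(c(30, 30, 30), each = nf), c(nf, 1, 3))
  pos[20:32, 1, ] <- matrix(rep(c(102, 100, 100), each = 13), 13, 3)
  met_b <- make_traj(pos, times = (0:100) * 500, box = sim_box(L))
  out2 <- classify_surface_diffusion(met_b, mac, cutoffs = 8)
  expect_equal(nrow(out2$segments), 1)
  expect_equal(out2$segments$partner, 1)
})

test_that("surface and bulk populations are separated and recovered", {
  # surface walker: angular diffusion on a sphere of radius 10 around a
  # single static bead (D_2D = Drot R^2); bulk walkers: free 3D diffusion
  set.seed(23)
  L <- 400; R0 <- 10; Drot <- 1e-4; D3 <- 0.05
  dtf <- 10; nf <- 4001
  cen <- c(200, 200, 200)
  ns <- 8
  co <- array(0, c(nf, ns + 4, 3))
  for (s in seq_len(ns)) {
    rot <- gen_rigid_rotor(Drot, dtf, nf - 1, seed = 30 + s)
    evec <- t(vapply(seq_len(nf), function(f)
      rot$rotations[f, , , 1] %*% c(1, 0, 0), numeric(3)))
    co[, s, ] <- sweep(R0 * evec, 2, cen, "+")
  }
  co[, ns + 1:4, ] <- gen_brownian_walkers(4, D3, dtf, nf - 1,
                                           seed = 32)$coords + 50
  met <- make_traj(co, times = (0:(nf - 1)) * dtf, box = sim_box(L))
  mac <- make_traj(array(rep(cen, each = nf), c(nf, 1, 3)),
                   times = (0:(nf - 1)) * dtf, box = sim_box(L))
  out <- classify_surface_diffusion(met, mac, cutoffs = 12,
                                    min_residence = 5000, tau_max = 250)
  # the stapled walkers are surface essentially everywhere away from ends
  expect_gt(mean(out$surface[, 1]), 0.4)
  expect_equal(sum(out$surface[, ns + 1:4]), 0)
  D2_true <- Drot * R0^2
  expect_lt(abs(out$D_surface - D2_true) / D2_true, 0.10)
  expect_lt(abs(out$D_bulk - D3) / D3, 0.10)
})

test_that("center-of-mass tracking reduces bead clusters to one walker", {
  # two beads rigidly offset: the molecule COM walks like one particle
  set.seed(91)
  base <- apply(array(rnorm(60 * 1 * 3, sd = 1.5), c(60, 1, 3)), c(2, 3),
                cumsum)
  co <- array(0, c(60, 2, 3))
  co[, 1, ] <- base[, 1, ] + 1.5
  co[, 2, ] <- base[, 1, ] - 1.5
  tr <- make_traj(co, times = (0:59) * 10,
                  molecule_index = c(1L, 1L))
  m_com <- compute_msd(tr, tau_max = 200, com_by_molecule = TRUE)
  ref <- make_traj(base, times = (0:59) * 10)
  m_ref <- compute_msd(ref, tau_max = 200)
  expect_equal(m_com$msd, m_ref$msd, tolerance = 1e-12)
})
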