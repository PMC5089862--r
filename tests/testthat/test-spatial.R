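test_that("accessible volume matches the analytic shell around one sphere", {
  box <- sim_box(100)
  av <- accessible_volume_profile(matrix(c(50, 50, 50), 1, 3), 10, box,
                                  r_max = 25, bin = 0.5)
  shell <- function(lo, hi) 4 / 3 * pi * ((10 + hi)^3 - (10 + lo)^3)
  sel <- av$r >= 2 & av$r < 20
  analytic <- shell(av$r[sel], av$r[sel] + 0.5)
  expect_true(all(abs(av$V[sel] - analytic) / analytic < 0.05))
  # excluded volume approximates the sphere itself
  expect_lt(abs(attr(av, "excluded") - 4 / 3 * pi * 1000) /
              (4 / 3 * pi * 1000), 0.05)
})

test_that("voxel partition conserves the box volume exactly", {
  set.seed(3)
  box <- sim_box(40)
  atoms <- matrix(runif(12, 5, 35), 4, 3)
  av <- accessible_volume_profile(atoms, c(3, 5, 4, 6), box, voxel = 1,
                                  r_max = 10, bin = 0.5)
  total <- attr(av, "excluded_voxels") + sum(attr(av, "voxel_counts")) +
    attr(av, "beyond_voxels")
  expect_identical(total, 40^3)
  # overlapping spheres: each voxel is assigned once (partition, so the
  # excluded volume is less than the sum of the two sphere volumes)
  two <- rbind(c(20, 20, 20), c(24, 20, 20))
  av2 <- accessible_volume_profile(two, c(5, 5), box, r_max = 10)
  expect_lt(attr(av2, "excluded"), 2 * 4 / 3 * pi * 125)
  expect_gt(attr(av2, "excluded"), 4 / 3 * pi * 125)
  expect_error(accessible_volume_profile(matrix(0, 0, 3), 1, box),
               "atoms")
})

test_that("ideal-gas metabolites give a flat proximal distribution", {
  # one fixed sphere (radius 10), fresh uniform metabolites every frame
  set.seed(41)
  L <- 70
  nf <- 50
  npts <- 34000
  co <- array(0, c(nf, npts + 1, 3))
  co[, 1, ] <- matrix(rep(c(35, 35, 35), each = nf), nf, 3)
  for (f in seq_len(nf)) co[f, -1, ] <- matrix(runif(3 * npts, 0, L),
                                               npts, 3)
  tab <- species_table(c("macro", "met"), c(10, 1), c(1, npts),
                       group = c("protein", "metabolite"))
  tr <- trajectory((seq_len(nf) - 1) * 10, co, c(1L, rep(2L, npts)), tab,
                   sim_box(L), wrapped = TRUE)
  g <- proximal_rdf(tr, metabolite_selection = "met",
                    macromolecule_selection = "macro", radii = 10,
                    plateau = c(20, 25))
  sel <- g$r >= 2
  expect_true(all(abs(g$g[sel] - 1) <= 0.05))
  expect_true(attr(g, "plateau_flat"))

  # doubling the metabolite count doubles rho but leaves g unchanged
  half <- trajectory(tr$times[1:10], co[1:10, 1:(npts / 2 + 1), ,
                                        drop = FALSE],
                     c(1L, rep(2L, npts / 2)), tab, sim_box(L),
                     wrapped = TRUE)
  full <- trajectory(tr$times[1:10], co[1:10, , , drop = FALSE],
                     tr$species_index, tab, sim_box(L), wrapped = TRUE)
  gh <- proximal_rdf(half, "met", "macro", radii = 10)
  gf <- proximal_rdf(full, "met", "macro", radii = 10)
  sel2 <- gh$n > 200 & gf$n > 200
  expect_equal(gf$rho[sel2] / gh$rho[sel2],
               rep(2, sum(sel2)), tolerance = 0.1)
  expect_equal(gf$g[sel2], gh$g[sel2], tolerance = 0.1)
})

test_that("point masses land in the right distance bin", {
  # 200 metabolites at exactly 5.2 A from the sphere surface, plus a
  # uniform background that populates the normalization plateau
  L <- 70
  set.seed(13)
  dirs <- matrix(rnorm(3 * 200), 200, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * 15.2, 2, c(35, 35, 35), "+")
  bg <- matrix(runif(3 * 2000, 0, L), 2000, 3)
  co <- array(0, c(1, 2201, 3))
  co[1, 1, ] <- c(35, 35, 35)
  co[1, 2:201, ] <- pts
  co[1, -(1:201), ] <- bg
  tab <- species_table(c("macro", "met"), c(10, 1), c(1, 2200),
                       group = c("protein", "metabolite"))
  tr <- trajectory(0, co, c(1L, rep(2L, 2200)), tab, sim_box(L),
                   wrapped = TRUE)
  g <- proximal_rdf(tr, "met", "macro", radii = 10, plateau = c(20, 25))
  expect_gte(g$n[g$r == 5.0], 200)     # the [5.0, 5.5) bin holds the spike
  expect_gt(g$g[g$r == 5.0], 5)        # far above the background level
  expect_gt(attr(g, "interacting_fraction"), 200 / 2200)

  # without any counts in the plateau, normalization must fail loudly
  co2 <- co[, 1:201, , drop = FALSE]
  tr2 <- trajectory(0, co2, c(1L, rep(2L, 200)), tab, sim_box(L),
                    wrapped = TRUE)
  expect_error(proximal_rdf(tr2, 2:201, 1, radii = 10), "plateau")
})

test_that("density grids accumulate in the body frame with symmetry", {
  # ligand rigidly co-moving with a tumbling target: all mass in one voxel
  template <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(-3, -3, -3))
  track <- gen_rigid_rotor(5e-4, 10, 60, seed = 21)
  nf <- 61
  co <- array(0, c(nf, 5, 3))
  off <- c(6.2, 0.2, 0.2)
  for (f in seq_len(nf)) {
    R <- track$rotations[f, , , 1]
    co[f, 1:4, ] <- template %*% t(R)
    co[f, 5, ] <- as.numeric(R %*% off)
  }
  tr <- make_traj(co, times = (0:60) * 10)
  dg <- density_grid3d(tr, 1:4, 5, reference = template, extent = 10)
  cnt <- attr(dg, "counts")
  expect_equal(sum(cnt), nf)           # total mass conserved
  expect_equal(max(cnt), nf)           # a single voxel holds every count

  # uniform ligand gas in the body frame stays statistically flat
  set.seed(55)
  nlig <- 400
  co2 <- array(0, c(40, 4 + nlig, 3))
  for (f in 1:40) {
    co2[f, 1:4, ] <- template
    co2[f, -(1:4), ] <- matrix(runif(3 * nlig, -8, 8), nlig, 3)
  }
  tr2 <- make_traj(co2, times = (0:39) * 10)
  dg2 <- density_grid3d(tr2, 1:4, 4 + seq_len(nlig),
                        reference = template, extent = 8)
  cnt2 <- attr(dg2, "counts")
  expect_equal(sum(cnt2), 40 * nlig)
  # Poisson flatness: variance/mean of voxel counts near 1
  expect_lt(abs(stats::var(as.vector(cnt2)) / mean(cnt2) - 1), 0.25)

  # a two-fold symmetry map makes a one-sided distribution exactly mirror
  co3 <- array(0, c(1, 5, 3))
  co3[1, 1:4, ] <- template
  co3[1, 5, ] <- c(4.3, 1.3, 0.3)
  tr3 <- make_traj(co3, times = 0)
  sym <- list(R = diag(c(-1, 1, 1)), t = c(0, 0, 0))
  dg3 <- density_grid3d(tr3, 1:4, 5, reference = template, extent = 8,
                        symmetry = sym)
  cnt3 <- attr(dg3, "counts")
  flipped <- cnt3[dim(cnt3)[1]:1, , ]
  expect_equal(cnt3, flipped)
  expect_equal(sum(cnt3), 2)

  # OpenDX writer emits a parseable scalar field
  f <- tempfile(fileext = ".dx")
  write_opendx(dg3, f)
  txt <- readLines(f)
  expect_true(any(grepl("gridpositions counts 16 16 16", txt)))
})
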