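test_that("coordination numbers count crowder atoms exactly", {
  # crafted frame: exactly 7 crowder beads inside the 50 A cutoff
  L <- 300
  cen <- c(150, 150, 150)
  near <- sweep(matrix(rnorm(21), 7, 3) * 5, 2, cen + c(30, 0, 0), "+")
  far <- sweep(matrix(rnorm(30), 10, 3) * 5, 2, cen + c(120, 0, 0), "+")
  co <- rbind(cen, near, far)
  tr <- make_traj(array(co, c(1, nrow(co), 3)), box = sim_box(L),
                  wrapped = TRUE)
  cs <- coordination_series(tr, target = 1, cutoff = 50, window = 0)
  expect_equal(cs$Nc, 7)

  # isolated target: zero throughout
  iso <- make_traj(array(rep(c(10, 10, 10, 250, 250, 250), each = 3),
                         c(3, 2, 3)), box = sim_box(L), wrapped = TRUE)
  cs0 <- coordination_series(iso, target = 1, cutoff = 50, window = 0)
  expect_true(all(cs0$Nc == 0))
  expect_error(coordination_series(tr, 1, reference_atoms = 1), "empty")

  # brute-force all-pairs recount on a 50-particle frame
  set.seed(19)
  co50 <- matrix(runif(150, 0, 100), 50, 3)
  tr50 <- make_traj(array(co50, c(1, 50, 3)), box = sim_box(100),
                    wrapped = TRUE)
  cs50 <- coordination_series(tr50, target = 7, cutoff = 30, window = 0)
  d <- sqrt(rowSums(mi_r(sweep(co50[-7, ], 2, co50[7, ]), 100)^2))
  expect_equal(cs50$Nc, sum(d <= 30))

  # metabolite mode measures from the center of mass with its own cutoff
  csm <- coordination_series(tr50, target = 7, cutoff = 25, window = 0,
                             mode = "metabolite")
  expect_equal(csm$Nc, sum(d <= 25))
})

test_that("pair distance changes implement the end-window arithmetic", {
  L <- 500
  nf <- 41
  co <- array(0, c(nf, 2, 3))
  co[, 1, ] <- matrix(rep(c(100, 100, 100), each = nf), nf, 3)
  # beta drifts from 60 A to 65 A separation linearly
  co[, 2, 1] <- 100 + seq(60, 65, length.out = nf)
  co[, 2, 2:3] <- 100
  tab <- species_table(c("p1", "p2"), c(20, 20), c(1, 1))
  tr <- trajectory((0:(nf - 1)) * 100, co, c(1, 2), tab, sim_box(L))
  rec <- pair_distance_change(tr, 1, 2, tau_short = 500)
  # endpoint means: first/last 6 frames of a linear ramp
  expect_equal(rec$delta_d, mean(seq(60, 65, length.out = nf)[36:41]) -
                 mean(seq(60, 65, length.out = nf)[1:6]))
  expect_equal(rec$r_bar_initial, 2 * rec$rc_initial / 40)

  # static pair: exactly zero; r_bar arithmetic: 60/((20+20)/2) = 3
  cs <- co; cs[, 2, 1] <- 160
  trs <- trajectory((0:(nf - 1)) * 100, cs, c(1, 2), tab, sim_box(L))
  rec2 <- pair_distance_change(trs, 1, 2, tau_short = 500)
  expect_equal(rec2$delta_d, 0)
  expect_equal(rec2$r_bar_initial, 3)
  expect_error(pair_distance_change(tr, 1, 2, tau_short = 2500),
               "half the trajectory")
})

test_that("group matrix is exact on constant input and recovers known drifts", {
  set.seed(29)
  L <- 1000
  tab <- species_table(c("pgk", "eno", "nox", "trna"),
                       c(30, 33, 28, 24), c(4, 4, 4, 4),
                       group = c("glycolytic", "glycolytic", "protein",
                                 "RNA"))
  sp <- rep(1:4, each = 4)
  n <- 16
  # a tight cluster: every pair's scaled distance stays below the cutoff
  # at both ends, so time reversal acts on identical qualifying sets
  base <- matrix(runif(3 * n, 480, 520), n, 3)
  nf <- 21
  # constant configuration: delta_d identically zero with zero SE
  cco <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) cco[f, , ] <- base
  ctr <- trajectory((0:(nf - 1)) * 50, cco, sp, tab, sim_box(L))
  m0 <- group_interaction_matrix(ctr, tau_short = 100, seed = 3)
  expect_true(all(abs(m0$delta_d[!is.na(m0$delta_d)]) < 1e-10))
  expect_true(all(m0$se[!is.na(m0$se)] == 0))

  # deterministic drift: every glycolytic pair converges by 5 A
  dco <- cco
  gly <- which(sp <= 2)
  cen <- colMeans(base[gly, ])
  for (f in seq_len(nf)) {
    shrink <- 1 - 0.05 * (f - 1) / (nf - 1)
    dco[f, gly, ] <- sweep(sweep(base[gly, ], 2, cen) * shrink, 2, cen,
                           "+")
  }
  dtr <- trajectory((0:(nf - 1)) * 50, dco, sp, tab, sim_box(L))
  md <- group_interaction_matrix(dtr, tau_short = 100, seed = 3)
  # all glycolytic-glycolytic pair distances shrank by ~5%
  expect_lt(md$delta_d["glycolytic", "glycolytic"], 0)
  expect_equal(md$delta_d["protein", "RNA"], 0, tolerance = 1e-10)

  # antisymmetry under time reversal
  rtr <- trajectory(dtr$times, dco[nf:1, , , drop = FALSE], sp, tab,
                    sim_box(L))
  mr <- group_interaction_matrix(rtr, tau_short = 100, seed = 3)
  expect_equal(mr$delta_d["glycolytic", "glycolytic"],
               -md$delta_d["glycolytic", "glycolytic"], tolerance = 1e-10)

  # selection by scaled distance: uniform rescaling of coordinates and
  # radii scales delta_d exactly and keeps the qualifying sets
  s <- 2.5
  stab <- tab; stab$stokes_radius <- tab$stokes_radius * s
  straj <- trajectory(dtr$times, dco * s, sp, stab, sim_box(L * s))
  ms <- group_interaction_matrix(straj, tau_short = 100, seed = 3)
  expect_equal(ms$delta_d, md$delta_d * s, tolerance = 1e-9)
})

test_that("non-interacting mixtures give delta_d consistent with zero", {
  # Independent slow walkers: no interactions, so group distance changes
  # must vanish within noise.  (Pairs are selected by initial proximity,
  # which gives free diffusion a small outward drift ~ 2 D t / r; the
  # fixture keeps D t small so that bias is buried in the resampling SE.)
  null_walkers <- function(n_per, seed, L) {
    tr <- gen_brownian_walkers(2 * n_per, 0.002, 10, 50, seed = seed,
                               box = sim_box(L))
    tr$table <- species_table(c("a", "b"), c(25, 30), c(n_per, n_per),
                              group = c("protein", "glycolytic"))
    tr$species_index <- rep(1:2, each = n_per)
    tr
  }
  m <- group_interaction_matrix(null_walkers(36, 55, 216),
                                tau_short = 50, seed = 5)
  for (a in rownames(m$delta_d)) for (b in colnames(m$delta_d)) {
    if (is.na(m$delta_d[a, b])) next
    expect_lt(abs(m$delta_d[a, b]), 2 * m$se[a, b] + 1e-9)
  }

  # resampling noise shrinks when the pair count quadruples
  m2 <- group_interaction_matrix(null_walkers(72, 56, 272),
                                 tau_short = 50, seed = 5)
  expect_lt(stats::median(m2$se, na.rm = TRUE),
            stats::median(m$se, na.rm = TRUE))
})

test_that("matrices combine with trajectory-length weights", {
  m1 <- list(delta_d = matrix(c(-2, 1, 1, 0), 2, 2,
                              dimnames = list(c("g", "p"), c("g", "p"))),
             se = matrix(0.1, 2, 2, dimnames = list(c("g", "p"),
                                                    c("g", "p"))),
             tau_short = 100, Rcut_range = c(2, 3))
  m2 <- m1; m2$delta_d <- m1$delta_d + 1
  class(m1) <- class(m2) <- "interaction_matrix"
  comb <- combine_interaction_matrices(list(m1, m2), weights = c(3, 1))
  expect_equal(comb$delta_d["g", "g"], (3 * -2 + 1 * -1) / 4)
  expect_equal(glycolytic_enzymes()[1], "HPRK")
  expect_length(glycolytic_enzymes(), 10)
})
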