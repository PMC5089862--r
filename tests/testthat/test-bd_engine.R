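test_that("half-harmonic pair energy matches its closed form", {
  p <- potential_params()
  # 5 kBT at sphere-sphere contact, any radii
  expect_equal(pair_energy(30, 10, 20, p)$energy, 5)
  expect_equal(pair_energy(125.3, 105, 20.3, p)$energy, 5)
  # zero exactly at the cutoff and beyond
  expect_equal(pair_energy(31, 10, 20, p)$energy, 0)
  expect_equal(pair_energy(200, 10, 20, p)$energy, 0)
  # direct evaluation half-way into the buffer
  expect_equal(pair_energy(30.5, 10, 20, p)$energy, 0.5 * 10 * 0.5^2)
  # continuous and once-differentiable at the cutoff
  eps <- 1e-7
  expect_lt(pair_energy(31 - eps, 10, 20, p)$energy, 1e-10)
  expect_lt(pair_energy(31 - eps, 10, 20, p)$force, 1e-5)
  # force is -dV/dr (numeric derivative check inside the buffer)
  h <- 1e-6
  num <- -(pair_energy(30.2 + h, 10, 20, p)$energy -
             pair_energy(30.2 - h, 10, 20, p)$energy) / (2 * h)
  expect_equal(pair_energy(30.2, 10, 20, p)$force, num, tolerance = 1e-5)
  expect_error(pair_energy(0, 10, 20, p), "singular")
})

test_that("configuration energy is non-negative and zero iff no contacts", {
  set.seed(8)
  for (rep in 1:5) {
    co <- matrix(runif(60, 0, 100), ncol = 3)
    radii <- runif(20, 2, 12)
    e <- system_energy(co, radii, box = sim_box(100))
    expect_gte(e$energy, 0)
    pr <- crowdbd:::cpp_pairs_within(co, 100, 2 * max(radii) + 1)
    touching <- any(pr$d < radii[pr$i] + radii[pr$j] + 1)
    expect_equal(e$energy > 1e-12, touching)
  }
})

test_that("BD drift term is exact and noiseless steps are deterministic", {
  bd <- bd_params(timestep = 8, scheme = "ermak_mccammon")
  co <- matrix(c(50, 50, 50), 1, 3)
  # zero force, zero noise: no motion
  out <- bd_step(co, 20, bd, noise = FALSE)
  expect_equal(out, co)
  # fixed external force, zero noise: dx = D F dt exactly
  Fm <- matrix(c(1, 0, -2), 1, 3)
  D <- stokes_einstein_D(20)
  out <- bd_step(co, 20, bd, noise = FALSE, forces = Fm)
  expect_equal(out - co, D * Fm * 8)
})

test_that("two-sphere equilibrium matches Boltzmann quadrature and the MC oracle", {
  # two spheres, radius 5, in a 40 A box: distance distribution inside
  # [8.5, 11.5] compared with exp(-V(r)) 4 pi r^2 quadrature and with a
  # Metropolis Monte-Carlo oracle
  L <- 40; a <- 5
  pot <- potential_params()
  sys <- list(coords = rbind(c(10, 10, 10), c(25, 10, 10)),
              radii = c(a, a), box = sim_box(L))
  edges <- seq(8.5, 11.5, by = 0.5)
  cond_probs <- function(r) {
    h <- hist(r[r >= min(edges) & r < max(edges)], breaks = edges,
              plot = FALSE)
    h$counts / sum(h$counts)
  }
  pair_r <- function(traj) {
    d <- traj$coords[, 1, ] - traj$coords[, 2, ]
    sqrt(rowSums(mi_r(d, L)^2))
  }
  # quadrature truth
  mid <- (head(edges, -1) + tail(edges, -1)) / 2
  dens <- vapply(mid, function(r) {
    f <- function(x) exp(-pair_energy(x, a, a, pot)$energy) * 4 * pi * x^2
    stats::integrate(f, r - 0.25, r + 0.25)$value
  }, numeric(1))
  truth <- dens / sum(dens)

  run_probs <- function(scheme, dt, steps = 6e5, stride = 20) {
    bd <- bd_params(timestep = dt, steps = steps, output_stride = stride,
                    seed = 21, scheme = scheme)
    cond_probs(pair_r(run_simulation(sys, bd, pot)))
  }
  # at the rule-based timestep (0.0005 a^2/D ~ 0.25 ps for a = 5 A)
  p_bd <- run_probs("iniesta_delatorre", 0.25)
  expect_lt(max(abs(p_bd - truth)), 0.03)

  # Metropolis oracle (independent sampler)
  set.seed(31)
  x <- sys$coords; rmc <- numeric(3e4); e_old <-
    system_energy(x, c(a, a), pot, sys$box)$energy
  for (s in seq_len(3e4)) {
    prop <- x + matrix(rnorm(6, sd = 1.2), 2, 3)
    e_new <- system_energy(prop, c(a, a), pot, sys$box)$energy
    if (runif(1) < exp(e_old - e_new)) { x <- prop; e_old <- e_new }
    d <- mi_r(x[1, ] - x[2, ], L)
    rmc[s] <- sqrt(sum(d^2))
  }
  p_mc <- cond_probs(rmc[-(1:2000)])
  expect_lt(max(abs(p_mc - truth)), 0.05)

  # discretization bias: at twice the rule-based timestep the second-order
  # predictor-corrector sits closer to the quadrature truth than the
  # first-order scheme
  p_em <- run_probs("ermak_mccammon", 0.5, 1.5e6)
  p_in <- run_probs("iniesta_delatorre", 0.5, 1.5e6)
  expect_lte(sum(abs(p_in - truth)), sum(abs(p_em - truth)) + 0.01)
})

test_that("simulations are reproducible and recover Stokes-Einstein diffusion", {
  sys <- list(coords = matrix(c(100, 100, 100), 1, 3), radii = 20,
              box = sim_box(200))
  bd <- bd_params(timestep = 8, steps = 1e6, output_stride = 10, seed = 5,
                  scheme = "ermak_mccammon")
  tr <- run_simulation(sys, bd)
  tr2 <- run_simulation(sys, bd)
  expect_identical(tr$coords, tr2$coords)   # same seed, bit-identical
  # single free particle: fitted D within 5% of kBT/(6 pi eta a)
  f <- fit_dtr(compute_msd(tr, tau_max = 8000, dt_i = 80))
  expect_lt(abs(f$D_tr - stokes_einstein_D(20)) / stokes_einstein_D(20),
            0.05)
})

test_that("timestep rule reproduces the 8 ps standard and scales cubically", {
  dt <- suggest_timestep(15.8)
  expect_lt(abs(dt - 8), 1)
  expect_equal(suggest_timestep(2 * 15.8) / dt, 8, tolerance = 1e-12)
  expect_error(suggest_timestep(0), "positive")
  expect_error(suggest_timestep(-3), "positive")
})

test_that("cell-list forces equal the all-pairs oracle exactly", {
  set.seed(13)
  for (rep in 1:4) {
    n <- sample(50:200, 1)
    L <- 120
    radii <- exp(runif(n, log(2), log(25)))
    co <- matrix(runif(3 * n, 0, L), ncol = 3)
    pot <- potential_params()
    cell <- system_energy(co, radii, pot, sim_box(L), use_cells = TRUE)
    brute <- system_energy(co, radii, pot, sim_box(L), use_cells = FALSE)
    expect_identical(cell$energy, brute$energy)
    expect_identical(cell$forces, brute$forces)
    # against the plain-R oracle
    ora <- forces_oracle_hh(co, radii, L)
    expect_equal(cell$energy, ora$energy, tolerance = 1e-12)
    expect_equal(cell$forces, ora$forces, tolerance = 1e-10)
  }
  # LJ form as well
  lj <- gen_lj_mixture("AD", seed = 2)
  radii <- lj$table$stokes_radius[lj$species_index]
  cell <- system_energy(lj$coords, radii, lj$potential, lj$box,
                        use_cells = TRUE)
  brute <- system_energy(lj$coords, radii, lj$potential, lj$box,
                         use_cells = FALSE)
  expect_identical(cell$energy, brute$energy)
  expect_identical(cell$forces, brute$forces)
})

test_that("far-field mobility has the closed-form blocks and is SPD", {
  C <- crowdbd:::kT_over_6pieta(298, 0.89)
  M <- rpy_mobility(matrix(c(0, 0, 0), 1, 3), 10)
  expect_equal(M, diag(3) * C / 10)

  # two equal spheres on the x axis: independent closed-form expansion
  a <- 6; r <- 30
  M2 <- rpy_mobility(rbind(c(0, 0, 0), c(r, 0, 0)), c(a, a))
  pref <- 3 / 4 * C / r
  para <- pref * ((1 + 2 * a^2 / (3 * r^2)) + (1 - 2 * a^2 / r^2))
  perp <- pref * (1 + 2 * a^2 / (3 * r^2))
  expect_equal(M2[1, 4], para)
  expect_equal(M2[2, 5], perp)
  expect_equal(M2[3, 6], perp)
  expect_equal(M2, t(M2))

  set.seed(17)
  repeat {
    co <- matrix(runif(60, 0, 200), 20, 3)
    radii <- runif(20, 3, 10)
    pr <- crowdbd:::cpp_pairs_within(co, 0, 25)
    if (!length(pr$i) || all(pr$d > radii[pr$i] + radii[pr$j])) break
  }
  M20 <- rpy_mobility(co, radii)
  ev <- eigen(M20, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  expect_error(rpy_mobility(rbind(c(0, 0, 0), c(5, 0, 0)), c(4, 4)),
               "overlap")
})

test_that("hydrodynamic scheme propagates dilute particles at Stokes-Einstein", {
  sys <- list(coords = rbind(c(30, 30, 30), c(160, 160, 160)),
              radii = c(10, 10), box = sim_box(200))
  bd <- bd_params(timestep = 8, steps = 4e4, output_stride = 4, seed = 9,
                  scheme = "fixman_rpy")
  tr <- run_simulation(sys, bd)
  f <- fit_dtr(compute_msd(tr, tau_max = 1600, dt_i = 32))
  expect_lt(abs(f$D_tr - stokes_einstein_D(10)) / stokes_einstein_D(10),
            0.10)
})
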