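test_that("random force obeys fluctuation-dissipation statistics", {
  expect_true(all(random_force(0, rep(1, 5), 300, 0.002) == 0))
  expect_true(all(random_force(1, rep(1, 5), 0, 0.002) == 0))
  set.seed(1)
  m <- rep(12, 334000)   # ~1e6 Gaussian draws
  f <- random_force(1, m, 300, 0.002)
  expected <- 2 * 1 * 12 * sg_units$kB_int * 300 / 0.002
  expect_equal(var(as.vector(f)), expected, tolerance = 0.01)
})

test_that("mid-step momentum follows its defining formula", {
  v <- matrix(c(0.1, -0.2, 0.3), 1, 3)
  m <- 5; dt <- 0.002
  expect_equal(half_momentum_p0(v, matrix(0, 1, 3), matrix(0, 1, 3),
                                0, m, dt), m * v)
  f <- matrix(c(4, 0, 0), 1, 3)
  expect_equal(half_momentum_p0(matrix(0, 1, 3), f, matrix(0, 1, 3),
                                1, m, dt), f * dt / 2)
  # independent hand substitution, all terms active
  g <- matrix(c(1, 2, 3), 1, 3)
  got <- half_momentum_p0(v, f, g, 0.7, m, dt)
  hand <- m * v + (f + g - 0.7 * m * v) * dt / 2
  expect_equal(got, hand, tolerance = 1e-15)
})

test_that("conservation factor vanishes when guiding does no work", {
  p0 <- matrix(c(1, 2, 2), 1, 3)
  expect_equal(conservation_factor(matrix(0, 1, 3), p0, 1, 0.002), 0)
  g_perp <- matrix(c(2, -1, 0), 1, 3)   # orthogonal to p0
  expect_equal(conservation_factor(g_perp, p0, 1, 0.002), 0)
  # near-zero momentum triggers the denominator guard
  expect_equal(conservation_factor(matrix(1e-8, 1, 3),
                                   matrix(1e-9, 1, 3), 1, 0.002), 0)
})

test_that("velocity update reduces to the expected limits", {
  v <- matrix(c(0.3, -0.1, 0.2), 1, 3)
  f <- matrix(c(10, 5, -2), 1, 3)
  m <- 4; dt <- 0.002
  # plain leap-frog kick
  expect_equal(velocity_update(v, f, matrix(0, 1, 3), 0, 0, m, dt),
               v + f * dt / m, tolerance = 1e-15)
  # force-free damping by (1 - x)/(1 + x)
  x <- (1 + 0.5) * dt / 2
  expect_equal(velocity_update(v, matrix(0, 1, 3), matrix(0, 1, 3),
                               1, 0.5, m, dt),
               v * (1 - x) / (1 + x), tolerance = 1e-15)
  expect_error(velocity_update(v, f, matrix(0, 1, 3), 0, -1001, m, dt),
               "instability")
  # telescoping positions
  expect_equal(position_update(matrix(1, 1, 3), matrix(0, 1, 3), dt),
               matrix(1, 1, 3))
})

test_that("leap-frog reproduces the damped harmonic oscillator", {
  fix <- make_harmonic_dimer(mass = 10, fc = 20, r0 = 1.5, stretch = 0.4)
  m <- 10; k_int <- 20 * sg_units$mv2_per_kcal
  gamma <- 2
  dt <- 0.0005
  cfg <- run_config("ld", gamma = gamma, temperature = 0, dt = dt,
                    tL = 0.2, nsteps = 2000, seed = 1, out_interval = 2000)
  sys <- sg_run(sg_system(fix$topology, fix$positions, cfg,
                          velocities = matrix(0, 2, 3)))
  sep <- sys$r[2, 1] - sys$r[1, 1]
  # relative coordinate: reduced mass mu = m/2, both spring and friction
  # act on it with k_int and gamma
  x_ref <- damped_oscillator_x(2000 * dt, 0.4, k_int, m / 2, gamma)
  expect_equal(sep - 1.5, x_ref, tolerance = 5e-3)
})

test_that("mode reductions are bitwise: SGLD->LD->MD and SGMD", {
  fix <- small_chain_fixture(seed = 8)
  v0 <- initialize_velocities(fix$topology, 300, seed = 9)
  run_mode <- function(mode, gamma = 1, lambda = 0.2) {
    cfg <- run_config(mode, lambda = lambda, mu = 0, gamma = gamma,
                      temperature = 300, dt = 0.002, tL = 0.2,
                      nsteps = 50, seed = 33, out_interval = 10)
    sg_run(sg_system(fix$topology, fix$positions, cfg, velocities = v0))
  }
  # guiding switched off: SGLD collapses onto LD bitwise
  expect_identical(run_mode("sgld", lambda = 0)$r, run_mode("ld")$r)
  # frictionless LD collapses onto MD bitwise
  expect_identical(run_mode("ld", gamma = 0)$r, run_mode("md")$r)
  # SGMD equals SGLD with gamma = 0 (no random force either way)
  expect_identical(run_mode("sgmd", gamma = 1)$r,
                   run_mode("sgld", gamma = 0)$r)
})

test_that("LD mode matches an independent Langevin reference bitwise", {
  fix <- make_lj_cluster(10, seed = 14)
  v0 <- initialize_velocities(fix$topology, 300, seed = 15)
  cfg <- run_config("ld", gamma = 1, temperature = 300, dt = 0.002,
                    tL = 0.2, nsteps = 100, seed = 44, out_interval = 100)
  sys <- sg_run(sg_system(fix$topology, fix$positions, cfg,
                          velocities = v0))
  ref <- ref_langevin(fix$topology, fix$positions, v0, gamma = 1,
                      temp = 300, dt = 0.002, nsteps = 100, seed = 44)
  expect_identical(sys$r, ref$positions)
  expect_identical(sys$v, ref$velocities)
})

test_that("a static force-free atom is a fixed point of the step", {
  top <- topology(mass = 5)
  cfg <- run_config("md", temperature = 0, dt = 0.002, tL = 0.2,
                    nsteps = 1, out_interval = 1)
  sys <- sg_system(top, matrix(1, 1, 3), cfg, velocities = matrix(0, 1, 3))
  sys2 <- sg_step(sys)
  expect_identical(sys2$r, sys$r)
  expect_identical(sys2$v, sys$v)
  expect_equal(sys2$t, 0.002)
})

test_that("runs are reproducible and log at the configured cadence", {
  fix <- small_chain_fixture(seed = 2)
  cfg <- run_config("sgld", nsteps = 55, seed = 21, out_interval = 10,
                    sg_type = 4, dL = 5)
  a <- sg_run(sg_system(fix$topology, fix$positions, cfg))
  b <- sg_run(sg_system(fix$topology, fix$positions, cfg))
  expect_identical(a$log, b$log)
  expect_equal(nrow(a$log), 55 %/% 10 + 1)
  expect_true(all(diff(a$log$time) > 0))
  # nsteps = 0: the initial record only
  cfg0 <- run_config("md", nsteps = 0)
  z <- sg_run(sg_system(fix$topology, fix$positions, cfg0))
  expect_equal(nrow(z$log), 1L)
})

test_that("guided runs hold the target temperature", {
  # eta removes the guiding energy input: SGLD stays near 300 K
  # (kinetic-temperature noise per snapshot is ~sqrt(2/3N) T, so a small
  # system needs a long averaging window)
  fix <- make_lj_cluster(60, seed = 3)
  cfg <- run_config("sgld", lambda = 0.2, tL = 0.2, gamma = 1,
                    temperature = 300, dt = 0.002, nsteps = 3000,
                    seed = 6, out_interval = 25)
  sys <- sg_run(sg_system(fix$topology, fix$positions, cfg))
  temps <- sys$log$tempK[sys$log$time > 2]
  expect_equal(mean(temps), 300, tolerance = 0.08)
})
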