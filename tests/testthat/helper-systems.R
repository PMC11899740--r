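# shared fixtures and independent reference implementations

# independent plain-Langevin leap-frog, coded separately from sg_step:
# draws one n-by-3 random force per step (column-wise rnorm) when
# gamma > 0 and T > 0, matching the package's documented RNG convention.
ref_langevin <- function(topology, positions, velocities, gamma, temp,
                         dt, nsteps, seed, boundary = NULL) {
  kB_int <- 0.0019872041 * 418.4
  scale <- 418.4
  m <- topology$mass
  n <- topology$n_atoms
  r <- positions
  v <- velocities
  set.seed(seed)
  x <- gamma * dt / 2
  for (s in seq_len(nsteps)) {
    ff <- compute_forces(topology, r)
    f <- ff$forces
    if (!is.null(boundary)) {
      f <- f + emap_energy_forces(boundary, r, m)$forces
    }
    f <- f * scale
    if (gamma > 0 && temp > 0) {
      sd <- sqrt(2 * gamma * m * kB_int * temp / dt)
      f <- f + matrix(rnorm(3L * n, 0, rep(sd, 3L)), n, 3L)
    }
    v <- ((1 - x) * v + f * (dt / m)) / (1 + x)
    r <- r + v * dt
  }
  list(positions = r, velocities = v)
}

# EMA iterated to steady state for a linearly moving input; closed-form
# checks use this as the brute-force oracle
iterate_ema_linear <- function(u, dt, tL, nsteps = 5000L) {
  r <- 0
  ravg <- 0
  for (s in seq_len(nsteps)) {
    r <- r + u * dt
    ravg <- (1 - dt / tL) * ravg + (dt / tL) * r
  }
  list(r = r, r_avg = ravg)
}

# analytic trajectory of an underdamped 1-D harmonic oscillator
# m x'' = -k_int x - gamma m x', released from rest at x0
damped_oscillator_x <- function(t, x0, k_int, m, gamma) {
  w0 <- sqrt(k_int / m)
  wd <- sqrt(w0^2 - gamma^2 / 4)
  exp(-gamma * t / 2) * x0 * (cos(wd * t) + gamma / (2 * wd) * sin(wd * t))
}

# tiny bonded test system: 3 chains x 4 beads, deterministic
small_chain_fixture <- function(seed = 11) {
  make_bead_chains(3, 4, 15, seed = seed, angle_fc = 10, eps = 0.6)
}

expect_matrix_equal <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(unname(a), unname(b))
  else expect_lt(max(abs(a - b)), tol)
}
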