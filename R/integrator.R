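#' Run configuration
#'
#' Collects all simulation parameters with the package defaults:
#' `dt = 0.002` ps, friction `gamma = 1`/ps, `lambda = 0.2`,
#' `tL = 0.2` ps, `dL = 5` \enc{Å}{A} and `tavg = tavg_factor * tL` with
#' `tavg_factor = 10`.  Modes: `"md"` (microcanonical, no friction or
#' random force, no guiding), `"ld"` (Langevin, no guiding), `"sgld"`
#' (Langevin plus guiding) and `"sgmd"` (guiding with `gamma` treated as
#' 0 and no random force).
#'
#' @param mode one of `"md"`, `"ld"`, `"sgld"`, `"sgmd"`.
#' @param lambda momentum guiding factor; ignored (forced to 0) for
#'   `md`/`ld`.  Use `balanced = TRUE` to set it to
#'   [balanced_lambda()]`(mu)`.
#' @param mu force guiding factor; forced to 0 for `md`/`ld`.
#' @param tL local average time (ps), must exceed `dt`.
#' @param tavg_factor friction averaging time in units of `tL`
#'   (`tavg = tavg_factor * tL`, must be >= 1).
#' @param sg_type spatial averaging type 1-4.
#' @param dL grid spacing for type 4 (\enc{Å}{A}).
#' @param gamma Langevin friction constant (1/ps), >= 0.
#' @param temperature target temperature (K).
#' @param dt time step (ps).
#' @param nsteps default number of steps for [sg_run()].
#' @param seed integer RNG seed for the run.
#' @param boundary `NULL`, or a list with `side`, `spacing`, `cmap`
#'   passed to [build_boundary_map()].
#' @param balanced logical; replace `lambda` by the balanced factor.
#' @param xi optional fixed per-atom apparent friction (1/ps) used
#'   instead of the on-the-fly estimate (e.g. read from a previous run).
#' @param out_interval steps between log/trajectory records.
#' @return object of class `sg_config`.
#' @export
run_config <- function(mode = c("sgld", "ld", "sgmd", "md"),
                       lambda = 0.2, mu = 0, tL = 0.2, tavg_factor = 10,
                       sg_type = 1L, dL = 5, gamma = 1, temperature = 300,
                       dt = 0.002, nsteps = 1000L, seed = 1L,
                       boundary = NULL, balanced = FALSE, xi = NULL,
                       out_interval = 10L) {
  mode <- match.arg(mode)
  stopifnot(tL > dt, tavg_factor >= 1, gamma >= 0, temperature >= 0,
            dt > 0, nsteps >= 0, sg_type %in% 1:4)
  if (sg_type == 4L && (!is.numeric(dL) || dL <= 0)) {
    stop("type 4 spatial averaging requires dL > 0")
  }
  if (balanced) {
    if (abs(mu) >= 1) {
      warning("balanced guiding requested with |mu| >= 1; ",
              "the balance relation is only mild for small |mu|")
    }
    lambda <- balanced_lambda(mu)
  }
  if (mode %in% c("md", "ld")) {
    lambda <- 0; mu <- 0
  }
  structure(list(
    mode = mode, lambda = lambda, mu = mu, tL = tL,
    tavg = tavg_factor * tL, sg_type = as.integer(sg_type), dL = dL,
    gamma = gamma, temperature = temperature, dt = dt,
    nsteps = as.integer(nsteps), seed = as.integer(seed),
    boundary = boundary, xi = xi, out_interval = as.integer(out_interval)
  ), class = "sg_config")
}

#' Read a run configuration from a plain-text key-value file
#'
#' The file holds `key: value` pairs (YAML subset); keys match
#' [run_config()] argument names, with `boundary_side`,
#' `boundary_spacing` and `boundary_cmap` expanded into the `boundary`
#' list and `xi_file` read through [read_xi()] into `xi`.  Unknown keys
#' are an error.
#'
#' @param path file path.
#' @param ... overrides applied after the file is read.
#' @return an `sg_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must hold key: value pairs: ", path)
  ov <- list(...)
  vals[names(ov)] <- ov
  if (!is.null(vals$xi_file)) {
    vals$xi <- read_xi(vals$xi_file)
    vals$xi_file <- NULL
  }
  bkeys <- c("boundary_side", "boundary_spacing", "boundary_cmap")
  if (any(bkeys %in% names(vals))) {
    vals$boundary <- list(
      side = vals$boundary_side %||% 20,
      spacing = vals$boundary_spacing %||% 4,
      cmap = vals$boundary_cmap %||% -1.0)
    vals[bkeys] <- NULL
  }
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Langevin random force
#'
#' Per-component Gaussian draws with variance
#' \eqn{2\gamma m k_B T/\delta t} in internal force units
#' (g/mol \enc{Å}{A}/ps\eqn{^2}, with `sg_units$kB_int`), the
#' fluctuation-dissipation partner of the friction \eqn{-\gamma m v}.
#' Exactly zero (and no RNG draws) when `gamma` or `T` is zero.
#' Draws fill the matrix column-wise: all x components, then y, then z.
#'
#' @param gamma friction constant (1/ps).
#' @param m per-atom masses (g/mol).
#' @param T temperature (K).
#' @param dt time step (ps).
#' @return n-by-3 force matrix (internal units).
#' @export
random_force <- function(gamma, m, T, dt) {
  stopifnot(gamma >= 0, T >= 0, dt > 0)
  n <- length(m)
  if (gamma == 0 || T == 0) return(matrix(0, n, 3L))
  sd <- sqrt(2 * gamma * m * sg_units$kB_int * T / dt)
  matrix(rnorm(3L * n, mean = 0, sd = rep(sd, 3L)), n, 3L)
}

#' Mid-step momentum estimate
#'
#' \deqn{p_0 = m v_{t-\delta t/2} +
#'       (f + g - \gamma m v_{t-\delta t/2})\,\delta t/2,}
#' the momentum the atom would have at the full step under the current
#' forces; used by the energy-conservation factor.
#'
#' @param v_prev velocities at \eqn{t-\delta t/2} (n-by-3).
#' @param f total force including any random force (internal units).
#' @param g guiding force (internal units).
#' @param gamma friction constant (1/ps).
#' @param m per-atom masses (g/mol).
#' @param dt time step (ps).
#' @return n-by-3 momentum matrix (g/mol \enc{Å}{A}/ps).
#' @export
half_momentum_p0 <- function(v_prev, f, g, gamma, m, dt) {
  v_prev * m + (f + g - gamma * (v_prev * m)) * (dt / 2)
}

#' Energy-conservation scaling factor
#'
#' \deqn{\eta = \frac{(2+\gamma\delta t)\, g\cdot p_0}
#'       {2 p_0\cdot p_0 - (g\cdot p_0)\,\delta t},}
#' an atom-specific velocity-damping rate that removes the net energy the
#' guiding force injects, so guided runs hold the target temperature.
#' \eqn{\eta = 0} when \eqn{g\cdot p_0 = 0} and whenever the denominator
#' magnitude falls below `guard` (near-zero momentum).
#'
#' @param g guiding force (n-by-3, internal units).
#' @param p0 mid-step momentum from [half_momentum_p0()].
#' @param gamma friction constant (1/ps).
#' @param dt time step (ps).
#' @param guard denominator floor (internal units).
#' @return per-atom \eqn{\eta} vector (1/ps).
#' @export
conservation_factor <- function(g, p0, gamma, dt, guard = 1e-12) {
  gp <- rowSums(g * p0)
  pp <- rowSums(p0 * p0)
  den <- 2 * pp - gp * dt
  eta <- numeric(length(gp))
  ok <- abs(den) >= guard & gp != 0
  eta[ok] <- (2 + gamma * dt) * gp[ok] / den[ok]
  eta
}

#' Leap-frog velocity update
#'
#' \deqn{v_{t+\delta t/2} = \frac{1-(\gamma+\eta)\delta t/2}
#'       {1+(\gamma+\eta)\delta t/2}\, v_{t-\delta t/2} +
#'       \frac{(f+g)}{1+(\gamma+\eta)\delta t/2}\,\frac{\delta t}{m}.}
#' With \eqn{\gamma = \eta = 0} and \eqn{g = 0} this reduces to the plain
#' leap-frog kick.
#'
#' @param v_prev velocities at \eqn{t-\delta t/2}.
#' @param f total force (internal units; includes random force).
#' @param g guiding force (internal units).
#' @param gamma friction constant (1/ps).
#' @param eta per-atom conservation factor (1/ps).
#' @param m per-atom masses (g/mol).
#' @param dt time step (ps).
#' @return n-by-3 velocity matrix at \eqn{t+\delta t/2}.
#' @export
velocity_update <- function(v_prev, f, g, gamma, eta, m, dt) {
  x <- (gamma + eta) * dt / 2
  if (any(x <= -1)) {
    stop("integrator instability: (gamma + eta) * dt / 2 <= -1 ",
         "(max |eta| = ", format(max(abs(eta))), " 1/ps)")
  }
  ((1 - x) * v_prev + (f + g) * (dt / m)) / (1 + x)
}

#' Leap-frog position update
#'
#' \eqn{r_{t+\delta t} = r_t + v_{t+\delta t/2}\,\delta t}.
#'
#' @param r positions at \eqn{t}.
#' @param v_next velocities at \eqn{t+\delta t/2}.
#' @param dt time step (ps).
#' @return n-by-3 position matrix.
#' @export
position_update <- function(r, v_next, dt) {
  r + v_next * dt
}

#' Assemble a simulation system
#'
#' Bundles topology, coordinates, velocities, configuration, boundary map
#' and the time-average/friction states, ready for [sg_step()] /
#' [sg_run()].  When `velocities` is `NULL` they are drawn at the
#' configured temperature with the run seed.
#'
#' @param topology an [topology()] object.
#' @param positions n-by-3 initial coordinates (\enc{Å}{A}).
#' @param config an [run_config()].
#' @param velocities n-by-3 initial velocities at \eqn{t-\delta t/2}, or
#'   `NULL`.
#' @param boundary an `sg_emap`, or `NULL` to build one from
#'   `config$boundary` (if set).
#' @return object of class `sg_system`.
#' @export
#' @examples
#' fix <- make_harmonic_dimer(stretch = 0.1)
#' sys <- sg_system(fix$topology, fix$positions,
#'                  run_config("md", temperature = 0, nsteps = 10))
#' sys <- sg_run(sys)
#' tail(sys$log, 2)
sg_system <- function(topology, positions, config, velocities = NULL,
                      boundary = NULL) {
  stopifnot(inherits(topology, "sg_topology"), inherits(config, "sg_config"))
  positions <- as.matrix(positions)
  if (is.null(velocities)) {
    velocities <- initialize_velocities(topology, config$temperature,
                                        config$seed)
  }
  velocities <- as.matrix(velocities)
  stopifnot(nrow(positions) == topology$n_atoms,
            nrow(velocities) == topology$n_atoms)
  if (is.null(boundary) && !is.null(config$boundary)) {
    b <- config$boundary
    boundary <- build_boundary_map(b$side, b$spacing, b$cmap %||% -1.0)
  }
  neigh <- NULL
  if (config$sg_type %in% c(2L, 3L)) {
    neigh <- bonded_neighborhoods(topology, config$sg_type)
  }
  if (!is.null(config$xi)) {
    config$xi <- rep_len(as.numeric(config$xi), topology$n_atoms)
  }
  ff <- compute_forces(topology, positions)
  Ep <- ff$energy
  if (!is.null(boundary)) {
    Ep <- Ep + emap_energy_forces(boundary, positions, topology$mass)$energy
  }
  structure(list(
    topology = topology, config = config, boundary = boundary,
    neigh = neigh,
    r = positions, v = velocities, v_prev = velocities,
    Ep = Ep, t = 0, step = 0L,
    tas = new_time_averages(positions, Ep, config$tL),
    fs = new_friction_state(topology$n_atoms, config$tavg),
    diag = list(xi_mean = 0, eta_mean = 0, conc = NA_real_)
  ), class = "sg_system")
}

#' @export
#' @method print sg_system
print.sg_system <- function(x, ...) {
  cat(sprintf(
    "sg_system: %d atoms, mode %s, step %d (t = %g ps), Ep = %.4f kcal/mol\n",
    x$topology$n_atoms, x$config$mode, x$step, x$t, x$Ep))
  invisible(x)
}

#' Advance the simulation by one step
#'
#' Executes one full cycle of the self-guided leap-frog algorithm:
#' (1) interaction + boundary forces plus the Langevin random force;
#' (2) local time averages and the low-frequency momentum/force
#' reconstruction; (3) spatial averaging; (4) apparent-friction update;
#' (5) guiding force; (6) mid-step momentum and energy-conservation
#' factor; (7) velocity update; (8) position update.  Random numbers are
#' drawn from the current RNG stream; use [sg_run()] for seeded runs.
#'
#' @param sys an [sg_system()].
#' @return the updated system.
#' @export
sg_step <- function(sys) {
  cfg <- sys$config
  top <- sys$topology
  m <- top$mass
  dt <- cfg$dt
  scale <- sg_units$mv2_per_kcal
  langevin <- cfg$mode %in% c("ld", "sgld")
  gamma <- if (cfg$mode %in% c("md", "sgmd")) 0 else cfg$gamma

  # (1) forces at t, in internal units; random force only in LD/SGLD
  ff <- compute_forces(top, sys$r)
  Ep <- ff$energy
  f <- ff$forces
  if (!is.null(sys$boundary)) {
    em <- emap_energy_forces(sys$boundary, sys$r, m)
    Ep <- Ep + em$energy
    f <- f + em$forces
  }
  f <- f * scale
  if (langevin && gamma > 0 && cfg$temperature > 0) {
    f <- f + random_force(gamma, m, cfg$temperature, dt)
  }

  # (2) local time averages, then momentum/force reconstruction
  tas <- update_time_averages(sys$tas, sys$r, Ep, dt)
  tas$p_avg_prev <- tas$p_avg
  tas$p_avg <- local_momentum(sys$r, tas$r_avg, m, cfg$tL)
  p_full <- reconstruct_momentum(tas$p_avg, tas$p_avg_prev, dt, cfg$tL)
  fav <- local_force_averages(sys$r, tas$r_avg, tas$r_avg2, p_full, m,
                              cfg$tL)
  dF <- fav$F_avg - fav$F_avg2

  # (3) spatial averaging
  sa <- spatial_average(tas$p_avg, dF, cfg$sg_type, m,
                        positions = sys$r, neigh = sys$neigh, dL = cfg$dL)

  # (4) apparent friction (a fixed xi, if supplied, overrides the
  #     on-the-fly estimate)
  fs <- update_friction(sys$fs, sa$p_hat, sa$dF_hat, dt)
  xi <- if (is.null(cfg$xi)) fs$xi else cfg$xi

  # (5) guiding force
  if (cfg$lambda == 0 && cfg$mu == 0) {
    g <- matrix(0, top$n_atoms, 3L)
    eta <- numeric(top$n_atoms)
  } else {
    g <- guiding_force(cfg$lambda, cfg$mu, xi, sa$p_hat, sa$dF_hat)
    # (6) energy-conservation factor
    p0 <- half_momentum_p0(sys$v, f, g, gamma, m, dt)
    eta <- conservation_factor(g, p0, gamma, dt)
  }

  # (7)-(8) velocity and position updates
  v_next <- velocity_update(sys$v, f, g, gamma, eta, m, dt)
  r_next <- position_update(sys$r, v_next, dt)

  sys$v_prev <- sys$v
  sys$v <- v_next
  sys$r <- r_next
  sys$Ep <- Ep
  sys$tas <- tas
  sys$fs <- fs
  sys$step <- sys$step + 1L
  sys$t <- sys$step * dt
  sys$diag <- list(
    xi_mean = mean(xi), eta_mean = mean(eta),
    conc = concertedness_index(sa$p_hat, tas$p_avg))
  sys
}

#' Run a simulation
#'
#' Seeds the RNG with `config$seed`, advances `nsteps` steps and records
#' a log row at step 0 and every `out_interval` steps: time, potential
#' energy and its local average, kinetic temperature (full-step
#' velocities, i.e. the mean of adjacent half-step values), mean apparent
#' friction, mean conservation factor, concertedness index and (for
#' multi-chain systems) the nematic order parameter.  Optionally writes
#' XYZ trajectory frames at the same interval.
#'
#' @param sys an [sg_system()].
#' @param nsteps number of steps; defaults to `config$nsteps`.
#' @param traj_file optional XYZ trajectory path.
#' @param log_file optional path for the tab-separated log.
#' @return the final system, with the log data frame in `$log`.
#' @export
sg_run <- function(sys, nsteps = NULL, traj_file = NULL, log_file = NULL) {
  stopifnot(inherits(sys, "sg_system"))
  cfg <- sys$config
  nsteps <- as.integer(nsteps %||% cfg$nsteps)
  interval <- max(1L, cfg$out_interval)
  set.seed(cfg$seed)

  top <- sys$topology
  has_chains <- n_chain_vectors(top) >= 2L
  nrec <- nsteps %/% interval + 1L
  log <- matrix(NA_real_, nrec, 10L,
                dimnames = list(NULL, c("time", "Ep", "Ep_avg", "Ep_avg2",
                                        "tempK", "lfke", "xi_mean",
                                        "eta_mean", "conc", "S")))
  rec <- function(row, sys) {
    vfull <- (sys$v + sys$v_prev) / 2
    log[row, ] <<- c(
      sys$t, sys$Ep, sys$tas$Ep_avg, sys$tas$Ep_avg2,
      kinetic_temperature(vfull, top$mass),
      lowfreq_kinetic_energy(sys$tas$p_avg, top$mass),
      sys$diag$xi_mean, sys$diag$eta_mean, sys$diag$conc,
      if (has_chains) nematic_order(chain_end_vectors(top, sys$r))
      else NA_real_)
    if (!is.null(traj_file)) {
      write_xyz(traj_file, sys$r, names = top$name, time = sys$t,
                append = sys$step > 0L)
    }
  }
  if (!is.null(traj_file) && file.exists(traj_file)) file.remove(traj_file)
  rec(1L, sys)
  row <- 1L
  if (nsteps > 0L) {
    tryCatch(
      for (s in seq_len(nsteps)) {
        sys <- sg_step(sys)
        if (s %% interval == 0L) {
          row <- row + 1L
          rec(row, sys)
        }
      },
      error = function(e) {
        stop(sprintf("step %d: %s", sys$step + 1L, conditionMessage(e)),
             call. = FALSE)
      })
  }
  sys$log <- as.data.frame(log)
  if (!is.null(log_file)) {
    write.table(sys$log, log_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  sys
}
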