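#' Build a molecular topology
#'
#' A topology bundles per-atom masses, chain assignments, the bonded terms
#' (harmonic bonds and angles, optional cosine dihedrals) and per-atom
#' Lennard-Jones parameters of the toy force field.  Nonbonded exclusions
#' (all 1-2 and 1-3 pairs) are derived from the bond list at construction
#' time and stored symmetrically.
#'
#' Energy conventions: bonds \eqn{V = \frac{1}{2} k (d - d_0)^2}, angles
#' \eqn{V = \frac{1}{2} k (\theta - \theta_0)^2}, dihedrals
#' \eqn{V = k (1 + \cos(n\phi - \phi_0))}, Lennard-Jones
#' \eqn{4\epsilon[(\sigma/d)^{12} - (\sigma/d)^6]} with
#' Lorentz-Berthelot mixing and a plain cutoff at \eqn{3\sigma_{ij}}.
#'
#' @param mass numeric vector of atomic masses (g/mol), all > 0.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `r0` (rest length, \enc{Å}{A}) and `fc` (force constant,
#'   kcal/mol/\enc{Å}{A}\eqn{^2}), or `NULL`.
#' @param angles data.frame with columns `i`, `j`, `k` (vertex `j`),
#'   `theta0` (rad) and `fc` (kcal/mol/rad\eqn{^2}), or `NULL`.
#' @param dihedrals data.frame with columns `i`, `j`, `k`, `l`, `fc`
#'   (kcal/mol), `mult` (integer periodicity) and `phase` (rad), or `NULL`.
#' @param eps,sigma per-atom Lennard-Jones well depth (kcal/mol) and
#'   diameter (\enc{Å}{A}); recycled to the number of atoms.
#' @param chain integer or character chain identifier per atom (recycled).
#' @param name atom names (recycled; default "C").
#' @return An object of class `sg_topology`.
#' @export
#' @examples
#' top <- topology(mass = c(12, 12), bonds = data.frame(i = 1, j = 2,
#'                 r0 = 1.5, fc = 100))
#' top$n_atoms
topology <- function(mass, bonds = NULL, angles = NULL, dihedrals = NULL,
                     eps = 0, sigma = 1, chain = 1L, name = "C") {
  mass <- as.numeric(mass)
  n <- length(mass)
  if (n < 1L) stop("topology needs at least one atom")
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("all masses must be finite and > 0")
  }
  chk_idx <- function(df, cols, what) {
    idx <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(idx) <- "integer"
    if (any(idx < 1L) || any(idx > n)) {
      stop(sprintf("%s indices out of range 1..%d", what, n))
    }
    if (any(apply(idx, 1L, anyDuplicated) > 0L)) {
      stop(sprintf("%s terms must reference distinct atoms", what))
    }
    idx
  }
  if (!is.null(bonds) && nrow(bonds)) {
    bonds <- as.data.frame(bonds)
    chk_idx(bonds, c("i", "j"), "bond")
    if (any(bonds$r0 < 0) || any(bonds$fc < 0)) {
      stop("bond r0 and fc must be >= 0")
    }
  } else bonds <- data.frame(i = integer(), j = integer(),
                             r0 = numeric(), fc = numeric())
  if (!is.null(angles) && nrow(angles)) {
    angles <- as.data.frame(angles)
    chk_idx(angles, c("i", "j", "k"), "angle")
  } else angles <- data.frame(i = integer(), j = integer(), k = integer(),
                              theta0 = numeric(), fc = numeric())
  if (!is.null(dihedrals) && nrow(dihedrals)) {
    dihedrals <- as.data.frame(dihedrals)
    chk_idx(dihedrals, c("i", "j", "k", "l"), "dihedral")
  } else dihedrals <- data.frame(i = integer(), j = integer(), k = integer(),
                                 l = integer(), fc = numeric(),
                                 mult = integer(), phase = numeric())

  eps <- rep_len(as.numeric(eps), n)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(eps < 0) || any(sigma <= 0)) stop("eps must be >= 0, sigma > 0")

  adj <- bond_adjacency(n, bonds)
  excl <- derive_exclusions(adj)
  top <- structure(list(
    n_atoms   = n,
    mass      = mass,
    chain     = rep_len(chain, n),
    name      = rep_len(name, n),
    bonds     = bonds,
    angles    = angles,
    dihedrals = dihedrals,
    eps       = eps,
    sigma     = sigma,
    adjacency = adj,
    exclusions = excl
  ), class = "sg_topology")
  # precompute the static LJ pair tables (mixing, cutoff, exclusion mask)
  # for systems small enough that dense n x n matrices are cheap
  if (n > 1L && n <= 1024L && any(eps > 0)) {
    sig <- outer(sigma, sigma, "+") / 2
    epsm <- sqrt(outer(eps, eps))
    elig <- upper.tri(epsm) & epsm > 0
    if (nrow(excl)) elig[excl] <- FALSE
    top$lj_cache <- list(elig = elig, sig2 = sig^2, eps = epsm,
                         cut2 = (3 * sig)^2)
  }
  top
}

# adjacency list of directly bonded (1-2) neighbours
bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (a in seq_len(n)) adj[[a]] <- integer()
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

# symmetric set of 1-2 and 1-3 pairs, stored once with i < j
derive_exclusions <- function(adj) {
  n <- length(adj)
  pairs <- list()
  for (i in seq_len(n)) {
    one2 <- adj[[i]]
    one3 <- setdiff(unique(unlist(adj[one2], use.names = FALSE)), i)
    ex <- union(one2, one3)
    ex <- ex[ex > i]
    if (length(ex)) pairs[[length(pairs) + 1L]] <- cbind(i, ex)
  }
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    dimnames(m) <- list(NULL, c("i", "j"))
    m
  } else matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j")))
}

#' @export
#' @method print sg_topology
print.sg_topology <- function(x, ...) {
  cat(sprintf(
    "sg_topology: %d atoms, %d chains, %d bonds, %d angles, %d dihedrals\n",
    x$n_atoms, length(unique(x$chain)), nrow(x$bonds), nrow(x$angles),
    nrow(x$dihedrals)))
  invisible(x)
}

#' Bead-spring multi-chain fixture
#'
#' Places `n_chains` semiflexible bead-spring chains at random positions and
#' orientations inside a cubic region of side `box_side` centred at the
#' origin, emulating a crowded box of short peptides.  Each chain is grown
#' as a worm-like walk with Gaussian bend fluctuations; a placement is
#' rejected when any bead comes closer than `clash_dist` to a bead it is not
#' bonded to.  Consecutive beads are connected by harmonic bonds and triples
#' by harmonic angles with a straight rest geometry, so the chains behave as
#' semiflexible rods.
#'
#' @param n_chains number of chains (>= 1).
#' @param n_beads beads per chain (>= 2).
#' @param box_side side of the cubic placement region (\enc{Å}{A}).
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param bond_length bond rest length (\enc{Å}{A}).
#' @param bond_fc bond force constant (kcal/mol/\enc{Å}{A}\eqn{^2}).
#' @param angle_fc angle force constant (kcal/mol/rad\eqn{^2}); rest angle
#'   is \eqn{\pi}, so the default gives extended, strand-like chains with
#'   bend fluctuations of about 0.25 rad at 300 K.
#' @param bend_sd standard deviation (rad) of the bend angle used when
#'   growing the initial walk (matched to `angle_fc` at 300 K).
#' @param mass bead mass (g/mol; default a residue-scale 100).
#' @param eps,sigma Lennard-Jones parameters per bead.
#' @param clash_dist minimum allowed distance (\enc{Å}{A}) between
#'   non-bonded beads at placement time.
#' @param max_attempts placement attempts per chain before giving up.
#' @return list with elements `topology` (class `sg_topology`) and
#'   `positions` (n-by-3 matrix, \enc{Å}{A}).
#' @export
#' @examples
#' fix <- make_bead_chains(4, 6, 20, seed = 1)
#' fix$topology
make_bead_chains <- function(n_chains, n_beads, box_side, seed,
                             bond_length = 2.0, bond_fc = 100,
                             angle_fc = 10, bend_sd = 0.25,
                             mass = 100, eps = 0.6, sigma = 1.6,
                             clash_dist = 1.2, max_attempts = 2000L) {
  stopifnot(n_chains >= 1L, n_beads >= 2L, box_side > 0)
  set.seed(seed)
  half <- box_side / 2
  n <- n_chains * n_beads
  pos <- matrix(NA_real_, n, 3L)
  placed <- 0L

  grow_chain <- function() {
    p <- matrix(0, n_beads, 3L)
    p[1L, ] <- runif(3L, -half, half)
    u <- rnorm(3L); u <- u / sqrt(sum(u^2))
    p[2L, ] <- p[1L, ] + bond_length * u
    if (n_beads > 2L) {
      for (b in 3L:n_beads) {
        # bend the previous direction by a Gaussian angle about a random axis
        ax <- rnorm(3L)
        ax <- ax - sum(ax * u) * u
        nrm <- sqrt(sum(ax^2))
        if (nrm < 1e-12) ax <- c(u[2L], -u[1L], 0) else ax <- ax / nrm
        th <- rnorm(1L, 0, bend_sd)
        u <- cos(th) * u + sin(th) * ax
        u <- u / sqrt(sum(u^2))
        p[b, ] <- p[b - 1L, ] + bond_length * u
      }
    }
    p
  }

  for (c_id in seq_len(n_chains)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- grow_chain()
      if (any(abs(p) > half)) next
      # clash against already placed beads
      if (placed > 0L) {
        dmin <- min(cross_min_dist(p, pos[seq_len(placed), , drop = FALSE]))
        if (dmin < clash_dist) next
      }
      # clash within the chain between non-bonded beads (separation >= 2)
      if (n_beads > 2L && self_clash(p, clash_dist)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(
        "could not place chain %d after %d attempts: box too small",
        c_id, max_attempts))
    }
    pos[placed + seq_len(n_beads), ] <- p
    placed <- placed + n_beads
  }

  bonds <- do.call(rbind, lapply(seq_len(n_chains), function(c_id) {
    off <- (c_id - 1L) * n_beads
    data.frame(i = off + seq_len(n_beads - 1L),
               j = off + 2L:n_beads,
               r0 = bond_length, fc = bond_fc)
  }))
  angles <- NULL
  if (n_beads >= 3L && angle_fc > 0) {
    angles <- do.call(rbind, lapply(seq_len(n_chains), function(c_id) {
      off <- (c_id - 1L) * n_beads
      data.frame(i = off + seq_len(n_beads - 2L),
                 j = off + 2L:(n_beads - 1L),
                 k = off + 3L:n_beads,
                 theta0 = pi, fc = angle_fc)
    }))
  }
  top <- topology(mass = rep(mass, n), bonds = bonds, angles = angles,
                  eps = eps, sigma = sigma,
                  chain = rep(seq_len(n_chains), each = n_beads),
                  name = "CA")
  list(topology = top, positions = pos)
}

# smallest distance between rows of a and rows of b
cross_min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

self_clash <- function(p, clash) {
  nb <- nrow(p)
  for (a in seq_len(nb - 2L)) {
    d <- cross_min_dist(p[a, , drop = FALSE],
                        p[(a + 2L):nb, , drop = FALSE])
    if (min(d) < clash) return(TRUE)
  }
  FALSE
}

#' Lennard-Jones cluster fixture
#'
#' Random placement of `n` identical LJ atoms (no bonded terms) in a cube
#' sized for a reduced number density `rho_star` (atoms per
#' \eqn{\sigma^3}), with a minimum-distance rejection criterion.
#'
#' @param n number of atoms.
#' @param seed integer seed.
#' @param eps,sigma LJ parameters (kcal/mol, \enc{Å}{A}).
#' @param mass atomic mass (g/mol; default argon-like 40).
#' @param rho_star reduced number density used to size the box.
#' @param min_dist minimum pair distance accepted at placement
#'   (\enc{Å}{A}; default \eqn{0.9\sigma}).
#' @param max_attempts placement attempts per atom.
#' @return list with `topology` and `positions`.
#' @export
make_lj_cluster <- function(n, seed, eps = 0.3, sigma = 2.5, mass = 40,
                            rho_star = 0.2, min_dist = 0.9 * sigma,
                            max_attempts = 5000L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  side <- (n / rho_star)^(1 / 3) * sigma
  half <- side / 2
  pos <- matrix(NA_real_, n, 3L)
  pos[1L, ] <- runif(3L, -half, half)
  for (a in seq_len(n)[-1L]) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- runif(3L, -half, half)
      d <- cross_min_dist(matrix(cand, 1L), pos[seq_len(a - 1L), , drop = FALSE])
      if (min(d) >= min_dist) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place LJ cluster: density too high")
    pos[a, ] <- cand
  }
  top <- topology(mass = rep(mass, n), eps = eps, sigma = sigma,
                  chain = 1L, name = "AR")
  list(topology = top, positions = pos)
}

#' Harmonic dimer fixture
#'
#' Two atoms joined by a single harmonic bond, the minimal oscillator test
#' system.  Its vibration has angular frequency
#' \eqn{\omega = \sqrt{k_{int}/\mu}} with reduced mass \eqn{\mu} and
#' \eqn{k_{int} = fc \times 418.4} in internal units.
#'
#' @param mass per-atom mass (g/mol), length 1 or 2.
#' @param fc bond force constant (kcal/mol/\enc{Å}{A}\eqn{^2}).
#' @param r0 rest length (\enc{Å}{A}).
#' @param stretch initial elongation beyond `r0` (\enc{Å}{A}).
#' @return list with `topology`, `positions`, and `omega`
#'   (angular frequency, rad/ps).
#' @export
make_harmonic_dimer <- function(mass = 12, fc = 50, r0 = 1.5, stretch = 0) {
  mass <- rep_len(mass, 2L)
  top <- topology(mass = mass,
                  bonds = data.frame(i = 1L, j = 2L, r0 = r0, fc = fc),
                  eps = 0, sigma = 1)
  pos <- rbind(c(0, 0, 0), c(r0 + stretch, 0, 0))
  mu <- prod(mass) / sum(mass)
  omega <- sqrt(fc * sg_units$mv2_per_kcal / mu)
  list(topology = top, positions = pos, omega = omega)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Per-component Gaussian draws with variance \eqn{k_B T / m} in internal
#' units, so that the kinetic temperature of a large sample recovers `T`.
#'
#' @param topology an `sg_topology`.
#' @param T temperature (K), >= 0.
#' @param seed integer seed.
#' @return n-by-3 matrix of velocities (\enc{Å}{A}/ps).
#' @export
#' @examples
#' fix <- make_harmonic_dimer()
#' v <- initialize_velocities(fix$topology, 300, seed = 7)
initialize_velocities <- function(topology, T, seed) {
  stopifnot(inherits(topology, "sg_topology"), T >= 0)
  set.seed(seed)
  n <- topology$n_atoms
  sd <- sqrt(sg_units$kB_int * T / topology$mass)
  matrix(rnorm(3L * n, mean = 0, sd = rep(sd, 3L)), n, 3L)
}
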