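#' Bonded neighbourhoods for spatial averaging
#'
#' Builds, once per topology, the neighbourhood sets \eqn{\Omega_i} used by
#' the bonded spatial-averaging types: type 2 collects atom `i` with its
#' 1-2 and 1-3 neighbours (bond-length and bond-angle atoms); type 3
#' additionally includes 1-4 neighbours (dihedral atoms), i.e. the local
#' chemical structure.  Sets derived from the (undirected) bond graph are
#' symmetric, and every set contains the atom itself.
#'
#' @param topology an [topology()] object with a bond list.
#' @param type 2 or 3.
#' @return object of class `sg_neighborhoods`: list with `type`, `sets`
#'   (list of sorted index vectors) and `W` (sparse membership matrix with
#'   unit weights, rows = atoms, cols = members).
#' @export
#' @examples
#' fix <- make_bead_chains(1, 4, 20, seed = 1)
#' bonded_neighborhoods(fix$topology, 2)$sets[[1]]
bonded_neighborhoods <- function(topology, type) {
  stopifnot(inherits(topology, "sg_topology"), type %in% c(2L, 3L))
  adj <- topology$adjacency
  n <- topology$n_atoms
  depth <- if (type == 2L) 2L else 3L
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    cur <- i
    seen <- i
    for (d in seq_len(depth)) {
      nxt <- unique(unlist(adj[cur], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      cur <- nxt
    }
    sets[[i]] <- sort(seen)
  }
  len <- lengths(sets)
  W <- Matrix::sparseMatrix(i = rep.int(seq_len(n), len),
                            j = unlist(sets, use.names = FALSE),
                            x = 1, dims = c(n, n))
  structure(list(type = as.integer(type), sets = sets, W = W),
            class = "sg_neighborhoods")
}

#' Mass-weighted average over neighbourhood sets
#'
#' \deqn{\hat q_i = m_i \frac{\sum_{j\in\Omega_i} \tilde q_j w_{ij}}
#'       {\sum_{j\in\Omega_i} m_j w_{ij}}}
#' with unit weights.  Motion shared by the set passes through
#' (\eqn{\hat q_i = m_i u} when \eqn{\tilde q_j = m_j u}); anti-parallel
#' contributions cancel.
#'
#' @param neigh an [bonded_neighborhoods()] object (or any
#'   `sg_neighborhoods`).
#' @param m per-atom masses (g/mol).
#' @param q n-by-3 per-atom quantity (e.g. low-frequency momentum).
#' @return n-by-3 matrix of spatially averaged values.
#' @export
average_over_sets <- function(neigh, m, q) {
  stopifnot(inherits(neigh, "sg_neighborhoods"))
  if (any(lengths(neigh$sets) == 0L)) stop("empty neighbourhood set")
  msum <- as.numeric(neigh$W %*% m)
  qsum <- as.matrix(neigh$W %*% as.matrix(q))
  qsum * (m / msum)
}

#' Project low-frequency atomic properties onto a grid
#'
#' Each atom deposits its mass, low-frequency momentum \eqn{\tilde p} and
#' force difference \eqn{\Delta\tilde F} onto the 8 grid points of its
#' cell with trilinear weights \eqn{(1-|x|)(1-|y|)(1-|z|)} in fractional
#' cell coordinates.  The grid fields are the mass-weighted velocities
#' \eqn{\hat v_g} and accelerations \eqn{\hat a_g}: deposited sums divided
#' by the deposited mass; grid points that received no mass carry zero
#' field.  The grid is anchored at multiples of `dL` one cell below the
#' coordinate minimum and rebuilt from the current positions.
#'
#' @param positions n-by-3 coordinates (\enc{Å}{A}).
#' @param m per-atom masses (g/mol).
#' @param p_avg n-by-3 low-frequency momenta.
#' @param dF n-by-3 low-frequency force differences.
#' @param dL grid spacing (\enc{Å}{A}), > 0.
#' @return object of class `sg_spatial_field`: list with `dims`, `origin`,
#'   `dL`, `mass` (deposited mass per grid point), `v`, `a`
#'   (G-by-3 matrices over grid points).
#' @export
grid_project <- function(positions, m, p_avg, dF, dL) {
  stopifnot(dL > 0)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  m <- rep_len(as.numeric(m), n)
  origin <- (floor(apply(positions, 2L, min) / dL) - 1) * dL
  g <- sweep(positions, 2L, origin) / dL
  c0 <- floor(g)
  fr <- g - c0
  dims <- as.integer(apply(c0, 2L, max) + 2L)  # 1-based grid size per axis
  G <- prod(dims)
  mass_g <- numeric(G)
  v_g <- matrix(0, G, 3L)
  a_g <- matrix(0, G, 3L)
  w_all <- numeric(8L * n)
  lin_all <- numeric(8L * n)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w_all[k + seq_len(n)] <-
      (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
      (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
      (if (dz) fr[, 3L] else 1 - fr[, 3L])
    lin_all[k + seq_len(n)] <- (c0[, 1L] + dx + 1) +
      dims[1L] * (c0[, 2L] + dy) +
      dims[1L] * dims[2L] * (c0[, 3L] + dz)
    k <- k + n
  }
  dep <- cbind(w_all * rep.int(m, 8L),
               w_all * p_avg[rep.int(seq_len(n), 8L), , drop = FALSE],
               w_all * dF[rep.int(seq_len(n), 8L), , drop = FALSE])
  s <- rowsum(dep, lin_all)
  at <- as.integer(rownames(s))
  mass_g[at] <- s[, 1L]
  v_g[at, ] <- s[, 2:4]
  a_g[at, ] <- s[, 5:7]
  occ <- mass_g > 0
  v_g[occ, ] <- v_g[occ, , drop = FALSE] / mass_g[occ]
  a_g[occ, ] <- a_g[occ, , drop = FALSE] / mass_g[occ]
  structure(list(dims = dims, origin = origin, dL = dL,
                 mass = mass_g, v = v_g, a = a_g),
            class = "sg_spatial_field")
}

#' Interpolate grid fields back to the atoms
#'
#' \deqn{\hat p_i = m_i \sum_g w_{ig} \hat v_g, \qquad
#'       \Delta\hat F_i = m_i \sum_g w_{ig} \hat a_g}
#' using the same trilinear weights as [grid_project()]; the field must
#' have been built from the same positions.
#'
#' @param field an `sg_spatial_field`.
#' @param positions n-by-3 coordinates the field was built from.
#' @param m per-atom masses (g/mol).
#' @return list with `p_hat` and `dF_hat` (n-by-3 matrices).
#' @export
grid_interpolate <- function(field, positions, m) {
  stopifnot(inherits(field, "sg_spatial_field"))
  positions <- as.matrix(positions)
  n <- nrow(positions)
  dims <- field$dims
  g <- sweep(positions, 2L, field$origin) / field$dL
  c0 <- floor(g)
  fr <- g - c0
  p_hat <- matrix(0, n, 3L)
  dF_hat <- matrix(0, n, 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
         (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
         (if (dz) fr[, 3L] else 1 - fr[, 3L])
    lin <- (c0[, 1L] + dx + 1) +
           dims[1L] * (c0[, 2L] + dy) +
           dims[1L] * dims[2L] * (c0[, 3L] + dz)
    p_hat <- p_hat + w * field$v[lin, , drop = FALSE]
    dF_hat <- dF_hat + w * field$a[lin, , drop = FALSE]
  }
  list(p_hat = p_hat * m, dF_hat = dF_hat * m)
}

#' Spatial averaging dispatcher
#'
#' Applies the configured spatial-averaging type to the low-frequency
#' momentum and force difference: type 1 is the identity (no spatial
#' averaging), types 2-3 average over bonded neighbourhoods, type 4 uses
#' trilinear grid projection and interpolation with spacing `dL`.
#'
#' @param p_avg,dF n-by-3 low-frequency momentum and force difference.
#' @param type averaging type, 1-4.
#' @param m per-atom masses (g/mol).
#' @param positions coordinates (required for type 4).
#' @param neigh `sg_neighborhoods` (required for types 2-3).
#' @param dL grid spacing (\enc{Å}{A}, required for type 4).
#' @return list with `p_hat`, `dF_hat`, and for type 4 the `field`.
#' @export
spatial_average <- function(p_avg, dF, type, m, positions = NULL,
                            neigh = NULL, dL = NULL) {
  type <- as.integer(type)
  if (type == 1L) {
    return(list(p_hat = as.matrix(p_avg), dF_hat = as.matrix(dF)))
  }
  if (type %in% c(2L, 3L)) {
    if (is.null(neigh)) stop("types 2-3 require bonded neighbourhoods")
    if (neigh$type != type) stop("neighbourhoods built for a different type")
    return(list(p_hat = average_over_sets(neigh, m, p_avg),
                dF_hat = average_over_sets(neigh, m, dF)))
  }
  if (type == 4L) {
    if (is.null(dL) || dL <= 0) stop("type 4 requires dL > 0")
    if (is.null(positions)) stop("type 4 requires positions")
    field <- grid_project(positions, m, p_avg, dF, dL)
    out <- grid_interpolate(field, positions, m)
    out$field <- field
    return(out)
  }
  stop("unknown spatial averaging type: ", type)
}
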