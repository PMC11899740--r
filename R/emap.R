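#' Build a boundary restraint map
#'
#' Constructs a cubic density map centred at the origin whose boundary
#' layer carries uniform density 1 and whose interior is zero.  A grid
#' point belongs to the boundary layer when its distance to the nearest
#' box face is at most one grid spacing.  Together with a negative
#' restraint constant `cmap` the map potential
#' \deqn{E_{map} = -c_{map} \sum_a m_a \hat\rho(x_a, y_a, z_a)}
#' repels atoms that approach the walls, confining a non-periodic system.
#'
#' @param side box side (\enc{Å}{A}); must exceed `2 * spacing` and be an
#'   integer multiple of `spacing`.
#' @param spacing grid spacing (\enc{Å}{A}).
#' @param cmap restraint constant (kcal/g); negative values repel.
#' @return An object of class `sg_emap`: list with `density` (3-D array),
#'   `spacing`, `origin` (coordinates of grid point \[1,1,1\]), `side`,
#'   `cmap`.
#' @export
#' @examples
#' bm <- build_boundary_map(20, 4, -1.0)
#' dim(bm$density)   # 6 x 6 x 6
build_boundary_map <- function(side, spacing, cmap = -1.0) {
  stopifnot(spacing > 0, side > 2 * spacing)
  np <- side / spacing
  if (abs(np - round(np)) > 1e-9) {
    stop("side must be an integer multiple of spacing")
  }
  np <- as.integer(round(np)) + 1L
  coords <- seq(0, side, by = spacing) - side / 2
  # distance of each axis position to the nearest face
  face_dist <- pmin(coords + side / 2, side / 2 - coords)
  is_bnd <- face_dist <= spacing + 1e-9
  dens <- array(0, dim = c(np, np, np))
  bx <- array(is_bnd, dim = c(np, np, np))
  by <- aperm(bx, c(2L, 1L, 3L))
  bz <- aperm(bx, c(3L, 2L, 1L))
  dens[bx | by | bz] <- 1
  if (all(dens > 0)) {
    warning("degenerate boundary map: no zero-density interior points")
  }
  structure(list(density = dens, spacing = spacing,
                 origin = rep(-side / 2, 3L), side = side, cmap = cmap),
            class = "sg_emap")
}

#' @export
#' @method print sg_emap
print.sg_emap <- function(x, ...) {
  cat(sprintf(
    "sg_emap: %s grid, spacing %g A, side %g A, cmap %g kcal/g, %d zero-interior points\n",
    paste(dim(x$density), collapse = "x"), x$spacing, x$side, x$cmap,
    sum(x$density == 0)))
  invisible(x)
}

#' Map potential energy and forces
#'
#' Evaluates \eqn{E_{map} = -c_{map} \sum_a m_a \hat\rho(r_a)} with
#' \eqn{\hat\rho} obtained by trilinear interpolation of the grid
#' densities, and the analytic negative gradient.  Atoms outside the grid
#' hull are clamped onto it for the interpolation, which leaves them under
#' the boundary-layer gradient at the clamp point (an inward restoring
#' force for repulsive maps).
#'
#' @param boundary an [build_boundary_map()] object.
#' @param positions n-by-3 coordinates (\enc{Å}{A}).
#' @param masses per-atom masses (g/mol).
#' @return list with `energy` (kcal/mol) and `forces`
#'   (n-by-3, kcal/mol/\enc{Å}{A}).
#' @export
emap_energy_forces <- function(boundary, positions, masses) {
  stopifnot(inherits(boundary, "sg_emap"))
  positions <- as.matrix(positions)
  n <- nrow(positions)
  masses <- rep_len(as.numeric(masses), n)
  dens <- boundary$density
  np <- dim(dens)
  h <- boundary$spacing

  # fractional grid coordinates, clamped to the hull
  g <- sweep(positions, 2L, boundary$origin) / h
  for (c_ in 1:3) g[, c_] <- pmin(pmax(g[, c_], 0), np[c_] - 1 - 1e-9)
  c0 <- pmin(floor(g), matrix(rep(np - 2L, each = n), n, 3L))
  fr <- g - c0
  c0 <- c0 + 1L  # 1-based lower corner

  rho <- numeric(n)
  grad <- matrix(0, n, 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) fr[, 1L] else 1 - fr[, 1L]
    wy <- if (dy) fr[, 2L] else 1 - fr[, 2L]
    wz <- if (dz) fr[, 3L] else 1 - fr[, 3L]
    dwx <- if (dx) 1 else -1
    dwy <- if (dy) 1 else -1
    dwz <- if (dz) 1 else -1
    dv <- dens[cbind(c0[, 1L] + dx, c0[, 2L] + dy, c0[, 3L] + dz)]
    rho <- rho + wx * wy * wz * dv
    grad[, 1L] <- grad[, 1L] + dwx * wy * wz * dv / h
    grad[, 2L] <- grad[, 2L] + wx * dwy * wz * dv / h
    grad[, 3L] <- grad[, 3L] + wx * wy * dwz * dv / h
  }
  energy <- -boundary$cmap * sum(masses * rho)
  forces <- boundary$cmap * grad * masses
  list(energy = energy, forces = forces, density = rho)
}

#' Read / write a boundary map as plain text
#'
#' Format: a header line `nx ny nz spacing ox oy oz cmap` followed by the
#' `nx*ny*nz` densities in x-fastest order, whitespace separated.
#'
#' @param path file path.
#' @param boundary an `sg_emap` object (for writing).
#' @return `read_boundary_map` returns an `sg_emap`;
#'   `write_boundary_map` returns `path` invisibly.
#' @export
write_boundary_map <- function(boundary, path) {
  stopifnot(inherits(boundary, "sg_emap"))
  hd <- c(dim(boundary$density), boundary$spacing, boundary$origin,
          boundary$cmap)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(format(hd, digits = 17), collapse = " "), con)
  writeLines(paste(format(as.vector(boundary$density), digits = 17),
                   collapse = " "), con)
  invisible(path)
}

#' @rdname write_boundary_map
#' @export
read_boundary_map <- function(path) {
  toks <- scan(path, what = numeric(), quiet = TRUE)
  if (length(toks) < 8L) stop("boundary map file too short: ", path)
  np <- as.integer(toks[1:3])
  spacing <- toks[4L]
  origin <- toks[5:7]
  cmap <- toks[8L]
  dens <- toks[-(1:8)]
  if (length(dens) != prod(np)) {
    stop(sprintf("boundary map %s: expected %d densities, found %d",
                 path, prod(np), length(dens)))
  }
  structure(list(density = array(dens, dim = np), spacing = spacing,
                 origin = origin, side = spacing * (np[1L] - 1L),
                 cmap = cmap),
            class = "sg_emap")
}
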