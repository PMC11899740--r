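#' Toy force field: energy and forces
#'
#' Sums harmonic bond, harmonic angle, optional cosine dihedral and
#' Lennard-Jones terms (with the topology's 1-2/1-3 exclusions and a plain
#' cutoff at \eqn{3\sigma_{ij}}) and returns the potential energy together
#' with the exact negative gradient.
#'
#' @param topology an [topology()] object.
#' @param positions n-by-3 coordinate matrix (\enc{Å}{A}).
#' @return list with `energy` (kcal/mol), `forces`
#'   (n-by-3, kcal/mol/\enc{Å}{A}) and a named `terms` energy breakdown.
#' @export
#' @examples
#' fix <- make_harmonic_dimer(stretch = 0.2)
#' compute_forces(fix$topology, fix$positions)$energy
compute_forces <- function(topology, positions) {
  if (!inherits(topology, "sg_topology")) stop("not an sg_topology")
  if (!is.matrix(positions)) positions <- as.matrix(positions)
  n <- topology$n_atoms
  if (!is.numeric(positions) || nrow(positions) != n || ncol(positions) != 3L)
    stop("positions must be an n-by-3 numeric matrix")
  if (!all(is.finite(positions))) stop("non-finite coordinates")

  f <- matrix(0, n, 3L)
  terms <- c(bond = 0, angle = 0, dihedral = 0, lj = 0)

  bd <- topology$bonds
  if (nrow(bd)) {
    rij <- positions[bd$j, , drop = FALSE] - positions[bd$i, , drop = FALSE]
    d <- sqrt(rowSums(rij^2))
    dd <- d - bd$r0
    terms["bond"] <- sum(0.5 * bd$fc * dd^2)
    # force on j is -fc*dd*unit(i->j)
    fm <- -bd$fc * dd / d
    f <- acc_pair(f, bd$i, bd$j, rij * fm)
  }

  an <- topology$angles
  if (nrow(an)) {
    a <- positions[an$i, , drop = FALSE] - positions[an$j, , drop = FALSE]
    b <- positions[an$k, , drop = FALSE] - positions[an$j, , drop = FALSE]
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2))
    ah <- a / la; bh <- b / lb
    ct <- pmin(1, pmax(-1, rowSums(ah * bh)))
    th <- acos(ct)
    st <- sqrt(pmax(1 - ct^2, 1e-12))
    dth <- th - an$theta0
    terms["angle"] <- sum(0.5 * an$fc * dth^2)
    dVdt <- an$fc * dth
    # dtheta/dri and dtheta/drk; vertex gets minus the sum
    gi <- (ct * ah - bh) / (la * st)
    gk <- (ct * bh - ah) / (lb * st)
    fi <- -dVdt * gi
    fk <- -dVdt * gk
    f <- acc_rows(f, an$i, fi)
    f <- acc_rows(f, an$k, fk)
    f <- acc_rows(f, an$j, -(fi + fk))
  }

  dh <- topology$dihedrals
  if (nrow(dh)) {
    res <- dihedral_terms(positions, dh)
    terms["dihedral"] <- res$energy
    f <- f + res$forces
  }

  if (any(topology$eps > 0) && n > 1L) {
    res <- lj_terms(topology, positions)
    terms["lj"] <- res$energy
    f <- f + res$forces
  }

  energy <- sum(terms)
  if (!is.finite(energy)) stop("non-finite energy: overlapping atoms?")
  list(energy = energy, forces = f, terms = terms)
}

# accumulate rows of `add` into `m` at (possibly repeated) indices
acc_rows <- function(m, idx, add) {
  if (!anyDuplicated(idx)) {
    m[idx, ] <- m[idx, , drop = FALSE] + add
    return(m)
  }
  s <- rowsum(add, idx)
  at <- as.integer(rownames(s))
  m[at, ] <- m[at, , drop = FALSE] + s
  m
}

# accumulate the equal-and-opposite pair forces (+add at j, -add at i)
acc_pair <- function(m, i, j, add) {
  s <- rowsum(rbind(add, -add), c(j, i))
  at <- as.integer(rownames(s))
  m[at, ] <- m[at, , drop = FALSE] + s
  m
}

# cosine dihedral V = fc (1 + cos(mult*phi - phase)); analytic gradient
dihedral_terms <- function(positions, dh) {
  n <- nrow(positions)
  b1 <- positions[dh$j, , drop = FALSE] - positions[dh$i, , drop = FALSE]
  b2 <- positions[dh$k, , drop = FALSE] - positions[dh$j, , drop = FALSE]
  b3 <- positions[dh$l, , drop = FALSE] - positions[dh$k, , drop = FALSE]
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  lb2 <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(rowcross(n1, n2) * (b2 / lb2))
  phi <- atan2(y, x)
  energy <- sum(dh$fc * (1 + cos(dh$mult * phi - dh$phase)))
  dVdphi <- -dh$fc * dh$mult * sin(dh$mult * phi - dh$phase)
  # standard leap of phi gradients (Blondel-Karplus form)
  gi <- -n1 * (lb2 / rowSums(n1^2))
  gl <-  n2 * (lb2 / rowSums(n2^2))
  s12 <- rowSums(b1 * b2) / lb2^2
  s32 <- rowSums(b3 * b2) / lb2^2
  gj <- -(1 + s12) * gi + s32 * gl
  gk <- -(1 + s32) * gl + s12 * gi
  f <- matrix(0, n, 3L)
  f <- acc_rows(f, dh$i, -dVdphi * gi)
  f <- acc_rows(f, dh$j, -dVdphi * gj)
  f <- acc_rows(f, dh$k, -dVdphi * gk)
  f <- acc_rows(f, dh$l, -dVdphi * gl)
  list(energy = energy, forces = f)
}

rowcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

lj_terms <- function(topology, positions) {
  n <- topology$n_atoms
  cache <- topology$lj_cache
  if (is.null(cache)) cache <- lj_pair_tables(topology)
  sq <- rowSums(positions^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(positions)
  idx <- which(cache$elig & d2 < cache$cut2)
  if (!length(idx)) {
    return(list(energy = 0, forces = matrix(0, n, 3L)))
  }
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  r2 <- pmax(d2[idx], 0)   # coincident atoms give infinite energy
  s2 <- cache$sig2[idx] / r2
  s6 <- s2^3
  e <- cache$eps[idx]
  energy <- sum(4 * e * (s6^2 - s6))
  # dV/dr2 * 2 => force on j along (rj - ri)
  fmag <- 24 * e * (2 * s6^2 - s6) / r2
  rij <- positions[j, , drop = FALSE] - positions[i, , drop = FALSE]
  f <- matrix(0, n, 3L)
  f <- acc_pair(f, i, j, rij * fmag)
  list(energy = energy, forces = f)
}

# fallback pair tables for large systems where no cache was stored
lj_pair_tables <- function(topology) {
  sig <- outer(topology$sigma, topology$sigma, "+") / 2
  epsm <- sqrt(outer(topology$eps, topology$eps))
  elig <- upper.tri(epsm) & epsm > 0
  if (nrow(topology$exclusions)) elig[topology$exclusions] <- FALSE
  list(elig = elig, sig2 = sig^2, eps = epsm, cut2 = (3 * sig)^2)
}
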