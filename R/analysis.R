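#' Kinetic temperature
#'
#' \eqn{T = 2\,KE/(3 N k_B)} with \eqn{KE = \sum_i m_i v_i^2/2/418.4}
#' kcal/mol.
#'
#' @param v n-by-3 velocity matrix (\enc{Å}{A}/ps).
#' @param m per-atom masses (g/mol).
#' @return temperature (K).
#' @export
#' @examples
#' kinetic_temperature(matrix(0, 5, 3), rep(1, 5))   # 0
kinetic_temperature <- function(v, m) {
  v <- as.matrix(v)
  n <- nrow(v)
  stopifnot(n >= 1L)
  sum(m * rowSums(v^2)) / (3 * n * sg_units$kB_int)
}

#' Kinetic energy of the low-frequency momentum
#'
#' \eqn{\sum_i |\tilde p_i|^2 / (2 m_i)} converted to kcal/mol: the
#' energy carried by the slow (diffusive/concerted) part of the motion.
#' Guided runs are expected to raise this quantity relative to plain
#' Langevin dynamics at the same temperature.
#'
#' @param p_avg n-by-3 low-frequency momentum matrix.
#' @param m per-atom masses (g/mol).
#' @return energy (kcal/mol).
#' @export
lowfreq_kinetic_energy <- function(p_avg, m) {
  sum(rowSums(as.matrix(p_avg)^2) / (2 * m)) / sg_units$mv2_per_kcal
}

#' Concertedness index
#'
#' Mean over atoms of \eqn{|\hat p|^2/|\tilde p|^2}: how much of each
#' atom's low-frequency motion is shared with its neighbourhood (1 for
#' fully concerted motion, small for incoherent motion).  Atoms with
#' negligible \eqn{|\tilde p|^2} are skipped.
#'
#' @param p_hat n-by-3 spatially averaged momenta.
#' @param p_avg n-by-3 low-frequency momenta.
#' @param floor squared-momentum floor below which atoms are skipped.
#' @return dimensionless index (NA when no atom qualifies).
#' @export
concertedness_index <- function(p_hat, p_avg, floor = 1e-12) {
  den <- rowSums(as.matrix(p_avg)^2)
  num <- rowSums(as.matrix(p_hat)^2)
  ok <- den > floor
  if (!any(ok)) return(NA_real_)
  mean(num[ok] / den[ok])
}

#' Per-chain end-to-end vectors
#'
#' @param topology an [topology()] object with chain identifiers.
#' @param positions n-by-3 coordinates.
#' @return matrix with one row per chain (chains with a single bead are
#'   dropped).
#' @export
chain_end_vectors <- function(topology, positions) {
  positions <- as.matrix(positions)
  ids <- unique(topology$chain)
  out <- lapply(ids, function(cid) {
    w <- which(topology$chain == cid)
    if (length(w) < 2L) return(NULL)
    positions[w[length(w)], ] - positions[w[1L], ]
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

n_chain_vectors <- function(topology) {
  tab <- table(topology$chain)
  sum(tab >= 2L)
}

#' Nematic order parameter
#'
#' Largest eigenvalue of the second-rank orientation tensor
#' \eqn{Q = \frac{3}{2}\langle \hat u \hat u^T\rangle - \frac{1}{2} I}
#' of the normalised input vectors.  `S = 1` for perfectly aligned (or
#' anti-aligned) vectors, `S -> 0` for an isotropic set; the measure is
#' invariant to flipping any vector, which makes it a suitable toy
#' surrogate for sheet-like chain alignment.
#'
#' @param vectors matrix with one direction vector per row (>= 2 rows).
#' @return order parameter in \[0, 1\].
#' @export
#' @examples
#' nematic_order(rbind(c(1, 0, 0), c(-1, 0, 0)))   # 1
nematic_order <- function(vectors) {
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) >= 2L)
  len <- sqrt(rowSums(vectors^2))
  keep <- len > 1e-12
  if (any(!keep)) {
    warning(sum(!keep), " zero-length vector(s) skipped")
    vectors <- vectors[keep, , drop = FALSE]
    len <- len[keep]
    if (nrow(vectors) < 2L) stop("fewer than 2 usable vectors")
  }
  u <- vectors / len
  q <- crossprod(u) / nrow(u)
  Q <- 1.5 * q - 0.5 * diag(3L)
  max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
}
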