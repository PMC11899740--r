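#' Initialise the apparent-friction state
#'
#' Two per-atom scalar accumulators, `FP` (running average of
#' \eqn{\Delta\hat F\cdot\hat p}) and `PP` (running average of
#' \eqn{\hat p\cdot\hat p}), start at zero and relax with time constant
#' `tavg` (typically ten local average times).  The apparent friction of
#' each atom is \eqn{\xi = -FP/PP}, or 0 while `PP` is below a small
#' floor (the cold-start guard for the division).
#'
#' @param n number of atoms.
#' @param tavg friction averaging time (ps).
#' @param pp_floor `PP` value below which \eqn{\xi} is reported as 0.
#' @return object of class `sg_friction` with fields `FP`, `PP`, `xi`,
#'   `tavg`, `pp_floor`.
#' @export
new_friction_state <- function(n, tavg, pp_floor = 1e-12) {
  stopifnot(n >= 1L, tavg > 0)
  structure(list(FP = numeric(n), PP = numeric(n), xi = numeric(n),
                 tavg = tavg, pp_floor = pp_floor),
            class = "sg_friction")
}

#' Update the apparent-friction accumulators
#'
#' \deqn{FP_t = (1-\delta t/t_{avg}) FP_{t-\delta t} +
#'       (\delta t/t_{avg})\, \Delta\hat F\cdot\hat p}
#' and likewise for `PP` with \eqn{\hat p\cdot\hat p}; then
#' \eqn{\xi = -FP/PP} per atom.  On the first update from a zero state
#' the \eqn{\delta t/t_{avg}} factors cancel in the ratio, so the initial
#' \eqn{\xi} does not depend on `tavg`.
#'
#' @param fs an `sg_friction` state.
#' @param p_hat n-by-3 spatially averaged low-frequency momenta.
#' @param dF_hat n-by-3 spatially averaged low-frequency force
#'   differences.
#' @param dt time step (ps), `<= tavg`.
#' @return updated `sg_friction` state.
#' @export
update_friction <- function(fs, p_hat, dF_hat, dt) {
  if (!inherits(fs, "sg_friction")) stop("not an sg_friction state")
  if (dt <= 0 || dt > fs$tavg) stop("need 0 < dt <= tavg")
  a <- dt / fs$tavg
  p_hat <- as.matrix(p_hat)
  fs$FP <- (1 - a) * fs$FP + a * rowSums(as.matrix(dF_hat) * p_hat)
  fs$PP <- (1 - a) * fs$PP + a * rowSums(p_hat^2)
  xi <- -fs$FP / fs$PP
  xi[!(fs$PP > fs$pp_floor)] <- 0
  fs$xi <- xi
  fs
}

#' Guiding force
#'
#' \deqn{g = \mu\,\Delta\hat F + \lambda\,\xi\,\hat p,}
#' the extra per-atom force that promotes low-frequency (and, with
#' spatial averaging, concerted) motion.  The momentum term uses the
#' apparent friction \eqn{\xi} to convert momentum into force units.
#'
#' @param lambda momentum guiding factor (dimensionless).
#' @param mu force guiding factor (dimensionless).
#' @param xi apparent friction (1/ps), scalar or per-atom vector.
#' @param p_hat n-by-3 spatially averaged momenta
#'   (g/mol \enc{Å}{A}/ps).
#' @param dF_hat n-by-3 spatially averaged force differences (internal
#'   units).
#' @return n-by-3 guiding force matrix (g/mol \enc{Å}{A}/ps\eqn{^2}).
#' @export
guiding_force <- function(lambda, mu, xi, p_hat, dF_hat) {
  mu * as.matrix(dF_hat) + lambda * xi * as.matrix(p_hat)
}

#' Balanced momentum guiding factor
#'
#' The momentum guiding factor \eqn{\lambda_\mu} at which the momentum-
#' and force-guiding effects cancel for a given force guiding factor
#' \eqn{\mu}:
#' \deqn{\lambda_\mu = \frac{\sqrt{1+\mu^2}-1}{1+\mu}.}
#' It vanishes at \eqn{\mu = 0} and is continuous for \eqn{\mu > -1}.
#'
#' @param mu force guiding factor, > -1.
#' @return balanced momentum guiding factor (dimensionless).
#' @export
#' @examples
#' balanced_lambda(0)      # 0
#' balanced_lambda(-0.2)
balanced_lambda <- function(mu) {
  if (any(mu <= -1)) stop("balanced_lambda requires mu > -1")
  (sqrt(1 + mu^2) - 1) / (1 + mu)
}

#' Read / write per-atom apparent frictions
#'
#' Plain whitespace-separated text, one value per atom, so frictions
#' estimated in one run can be supplied to a later one
#' (`run_config(xi = read_xi(path))`) instead of being re-estimated on
#' the fly.
#'
#' @param path file path.
#' @param xi numeric vector of apparent frictions (1/ps).
#' @return `read_xi` returns a numeric vector; `write_xi` returns `path`
#'   invisibly.
#' @export
write_xi <- function(xi, path) {
  writeLines(paste(format(as.numeric(xi), digits = 17), collapse = " "),
             path)
  invisible(path)
}

#' @rdname write_xi
#' @export
read_xi <- function(path) {
  xi <- scan(path, what = numeric(), quiet = TRUE)
  if (!length(xi) || any(!is.finite(xi))) {
    stop("invalid xi file: ", path)
  }
  xi
}
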