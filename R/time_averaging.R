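#' Exponential running (local time) average update
#'
#' One step of the discrete recursion
#' \deqn{\tilde P_t = (1 - \delta t/t_L)\,\tilde P_{t-\delta t} +
#'       (\delta t/t_L)\,P_t,}
#' the local time average whose time constant \eqn{t_L} sets a frequency
#' threshold \eqn{1/t_L}: components faster than this are attenuated,
#' slower ones pass through.  Applied elementwise to vectors/matrices.
#'
#' @param prev previous average \eqn{\tilde P_{t-\delta t}}.
#' @param current instantaneous value \eqn{P_t}.
#' @param dt time step (ps), `0 < dt <= tL`.
#' @param tL local average time (ps).
#' @return updated average, same shape as `prev`.
#' @export
#' @examples
#' ema_update(0, 2, dt = 0.1, tL = 0.2)   # 1
ema_update <- function(prev, current, dt, tL) {
  if (dt <= 0 || tL <= 0 || dt > tL) {
    stop("invalid averaging times: need 0 < dt <= tL")
  }
  a <- dt / tL
  (1 - a) * prev + a * current
}

#' Initialise a time-average state
#'
#' At step 0 the position averages equal the initial coordinates, the
#' energy averages equal the initial potential energy, and the
#' low-frequency momentum is zero, so guiding forces start at zero and
#' grow smoothly.
#'
#' @param positions initial n-by-3 coordinates.
#' @param Ep initial potential energy (kcal/mol).
#' @param tL local average time (ps).
#' @return object of class `sg_tavg` with fields `r_avg`, `r_avg2`
#'   (first- and second-order position averages), `p_avg`, `p_avg_prev`
#'   (low-frequency momentum, g/mol \enc{Å}{A}/ps), `Ep_avg`, `Ep_avg2`,
#'   `tL`.
#' @export
new_time_averages <- function(positions, Ep, tL) {
  positions <- as.matrix(positions)
  stopifnot(tL > 0, is.finite(Ep), all(is.finite(positions)))
  structure(list(
    r_avg = positions, r_avg2 = positions,
    p_avg = matrix(0, nrow(positions), 3L),
    p_avg_prev = matrix(0, nrow(positions), 3L),
    Ep_avg = Ep, Ep_avg2 = Ep, tL = tL
  ), class = "sg_tavg")
}

#' Advance the local time averages one step
#'
#' Updates the energy averages and then the position averages; the
#' second-order averages use the freshly updated first-order value as
#' their input (a second-order cascade), so the update order matters.
#'
#' @param tas an `sg_tavg` state.
#' @param positions current coordinates.
#' @param Ep current potential energy (kcal/mol).
#' @param dt time step (ps).
#' @return updated `sg_tavg` state.
#' @export
update_time_averages <- function(tas, positions, Ep, dt) {
  if (!inherits(tas, "sg_tavg")) stop("not an sg_tavg state")
  tL <- tas$tL
  tas$Ep_avg  <- ema_update(tas$Ep_avg, Ep, dt, tL)
  tas$Ep_avg2 <- ema_update(tas$Ep_avg2, tas$Ep_avg, dt, tL)
  tas$r_avg   <- ema_update(tas$r_avg, positions, dt, tL)
  tas$r_avg2  <- ema_update(tas$r_avg2, tas$r_avg, dt, tL)
  tas
}

#' Low-frequency momentum from position averages
#'
#' \deqn{\tilde p = (m/t_L)(r - \tilde r).}
#' This identity means only the position averages need to be stored to
#' recover the low-frequency momentum.
#'
#' @param positions current coordinates (\enc{Å}{A}).
#' @param r_avg first-order position average.
#' @param m per-atom masses (g/mol).
#' @param tL local average time (ps).
#' @return n-by-3 momentum matrix (g/mol \enc{Å}{A}/ps).
#' @export
local_momentum <- function(positions, r_avg, m, tL) {
  stopifnot(tL > 0)
  (as.matrix(positions) - as.matrix(r_avg)) * (m / tL)
}

#' Reconstruct the instantaneous momentum from consecutive averages
#'
#' \deqn{p_t = \tilde p_{t-\delta t} +
#'       (t_L/\delta t)(\tilde p_t - \tilde p_{t-\delta t}).}
#'
#' @param p_avg_now,p_avg_prev low-frequency momenta at the current and
#'   previous step.
#' @param dt time step (ps).
#' @param tL local average time (ps).
#' @return n-by-3 momentum matrix.
#' @export
reconstruct_momentum <- function(p_avg_now, p_avg_prev, dt, tL) {
  p_avg_prev + (tL / dt) * (p_avg_now - p_avg_prev)
}

#' Low-frequency force averages from position averages
#'
#' \deqn{\tilde F = p/t_L - (m/t_L^2)(r - \tilde r), \qquad
#'       \tilde{\tilde F} = (m/t_L^2)(r - 2\tilde r + \tilde{\tilde r}).}
#' Both come out in internal force units (g/mol \enc{Å}{A}/ps\eqn{^2});
#' their difference \eqn{\Delta\tilde F} is the low-frequency force signal
#' used for guiding.
#'
#' @param positions current coordinates.
#' @param r_avg,r_avg2 first- and second-order position averages.
#' @param p reconstructed momentum at the current step
#'   (from [reconstruct_momentum()]).
#' @param m per-atom masses (g/mol).
#' @param tL local average time (ps).
#' @return list with `F_avg`, `F_avg2` (n-by-3 matrices).
#' @export
local_force_averages <- function(positions, r_avg, r_avg2, p, m, tL) {
  r <- as.matrix(positions)
  F_avg <- p / tL - (r - as.matrix(r_avg)) * (m / tL^2)
  F_avg2 <- (r - 2 * as.matrix(r_avg) + as.matrix(r_avg2)) * (m / tL^2)
  list(F_avg = F_avg, F_avg2 = F_avg2)
}
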