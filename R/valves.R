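#' Heart valve parameters
#'
#' @param EOA effective orifice area of the valve, cm^2.
#' @param A_down downstream (aortic) cross-sectional area, cm^2. Required for
#'   the aortic valve, where the net gradient accounts for pressure recovery;
#'   `NA` for the mitral valve.
#' @param rho blood density, g/mL.
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(EOA, A_down = NA_real_, rho = 1.06) {
  if (!is.numeric(EOA) || length(EOA) != 1L || !is.finite(EOA) || EOA <= 0)
    stop("valve_params: EOA must be a positive scalar")
  if (rho <= 0) stop("valve_params: rho must be positive")
  if (!is.na(A_down) && A_down <= EOA)
    stop("valve_params: downstream area must exceed EOA")
  structure(list(EOA = EOA, A_down = A_down, rho = rho),
            class = "valve_params")
}

# 1 mmHg in dyne/cm^2; valve formulas work in CGS internally.
MMHG_PER_DYNE_CM2 <- 1 / 1333.22

#' Energy-loss coefficient of a valve with pressure recovery
#'
#' `ELCo = EOA * A / (A - EOA)`: the effective area governing the *net*
#' (recovered) transvalvular pressure gradient. As the orifice approaches the
#' downstream area the coefficient diverges and the net gradient vanishes
#' (full pressure recovery).
#'
#' @param v a [valve_params()] object with a finite downstream area.
#' @return Energy-loss coefficient, cm^2.
#' @export
energy_loss_coefficient <- function(v) {
  stopifnot(inherits(v, "valve_params"))
  if (is.na(v$A_down)) stop("energy_loss_coefficient: A_down is not set")
  if (v$EOA >= v$A_down)
    stop("energy_loss_coefficient: EOA must be below the downstream area")
  v$EOA * v$A_down / (v$A_down - v$EOA)
}

#' Net transvalvular pressure gradient at the aortic valve
#'
#' Net (post-recovery) gradient across the aortic valve as a function of the
#' transvalvular flow rate, its time derivative, the effective orifice area
#' and the aortic cross-sectional area:
#' \deqn{\Delta P_{net} = \frac{2\pi\rho}{\sqrt{2\,ELCo}}\,\dot Q
#'       + \frac{\rho}{2\,ELCo^2} Q^2}
#' with the energy-loss coefficient \eqn{ELCo = EOA\,A/(A-EOA)}. Both terms
#' are evaluated in CGS units and converted to mmHg (1 mmHg = 1333.22
#' dyne/cm^2).
#'
#' @param Q transvalvular flow, mL/s (valve open, `Q >= 0`).
#' @param dQdt flow acceleration, mL/s^2.
#' @param v a [valve_params()] object with `A_down` set.
#' @return Net pressure gradient, mmHg (vectorized over `Q` and `dQdt`).
#' @export
aortic_valve_gradient <- function(Q, dQdt, v) {
  elco <- energy_loss_coefficient(v)
  k_i <- 2 * pi * v$rho / sqrt(2 * elco)
  (k_i * dQdt + v$rho * Q^2 / (2 * elco^2)) * MMHG_PER_DYNE_CM2
}

#' Transvalvular pressure gradient at the mitral valve
#'
#' Bernoulli orifice loss `rho * Q^2 / (2 * EOA^2)` plus an inertial term
#' proportional to the flow acceleration. No pressure-recovery correction is
#' applied (its effect on the transmitral gradient is negligible in healthy
#' subjects), so the orifice area enters directly rather than through an
#' energy-loss coefficient.
#'
#' @inheritParams aortic_valve_gradient
#' @param M inertial coefficient, mmHg s^2/mL. Defaults to the same shape as
#'   the aortic inertial coefficient with EOA in place of ELCo.
#' @return Pressure gradient, mmHg.
#' @export
mitral_valve_gradient <- function(Q, dQdt, v, M = NULL) {
  stopifnot(inherits(v, "valve_params"))
  if (is.null(M))
    M <- 2 * pi * v$rho / sqrt(2 * v$EOA) * MMHG_PER_DYNE_CM2
  v$rho * Q^2 / (2 * v$EOA^2) * MMHG_PER_DYNE_CM2 + M * dQdt
}

#' Smoothed valve open fraction
#'
#' A valve behaves as a diode: open (1) when the upstream pressure exceeds
#' the downstream pressure or while forward flow persists, closed (0)
#' otherwise. The pressure transition is smoothed over a configurable width
#' so the ODE right-hand side stays continuous; while forward flow persists
#' the valve is held open so that flow decelerates naturally through an
#' adverse gradient (late-systolic flow deceleration).
#'
#' @param P_up upstream pressure, mmHg.
#' @param P_down downstream pressure, mmHg.
#' @param Q current valve flow, mL/s.
#' @param width pressure smoothing width, mmHg.
#' @param q_width flow smoothing width, mL/s.
#' @return Open fraction in \[0, 1\].
#' @export
valve_state <- function(P_up, P_down, Q, width = 0.1, q_width = 1) {
  sp <- 0.5 * (1 + tanh((P_up - P_down) / width))
  ifelse(Q <= 0, sp, 1 - (1 - sp) * (1 - tanh(Q / q_width)))
}
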