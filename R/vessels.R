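#' Viscoelastic vessel segment parameters
#'
#' A lumped vessel segment combines a frictional resistance `R` and an
#' inertance `L` in the flow path with a viscoelastic wall branch: a
#' compliance `C` in series with a wall resistance `Rv` (Voigt-type), hanging
#' from the segment's pressure node.
#'
#' @param R frictional resistance, mmHg s/mL.
#' @param Rv viscoelastic wall resistance, mmHg s/mL.
#' @param C compliance, mL/mmHg.
#' @param L inertance, mmHg s^2/mL.
#' @return An object of class `vessel_segment_params`.
#' @export
vessel_segment_params <- function(R, Rv, C, L) {
  v <- list(R = R, Rv = Rv, C = C, L = L)
  if (any(!vapply(v, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1))))
    stop("vessel_segment_params: R, Rv, C, L must all be positive scalars")
  structure(v, class = "vessel_segment_params")
}

#' Three-element viscoelastic Windkessel parameters
#'
#' Terminal load representing the systemic vascular bed down to the
#' capillaries: a peripheral resistance `R_p` toward the distal pressure
#' `P_out`, in parallel with a storage branch (`Rv_wk` in series with
#' `C_wk`).
#'
#' @param R_p peripheral resistance, mmHg s/mL.
#' @param C_wk compliance, mL/mmHg.
#' @param Rv_wk viscoelastic resistance in series with the compliance,
#'   mmHg s/mL (may be 0).
#' @param P_out distal outflow pressure, mmHg.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(R_p, C_wk, Rv_wk = 0, P_out = 0) {
  if (R_p <= 0 || C_wk <= 0 || Rv_wk < 0)
    stop("windkessel_params: need R_p > 0, C_wk > 0, Rv_wk >= 0")
  structure(list(R_p = R_p, C_wk = C_wk, Rv_wk = Rv_wk, P_out = P_out),
            class = "windkessel_params")
}

#' Vessel-segment state derivatives
#'
#' The segment's viscoelastic node is fed by `Q_in`; the segment flow `Q`
#' leaves the node through the series R-L branch toward the downstream
#' pressure. The node obeys `dV_c/dt = Q_in - Q` with node pressure
#' `P_c = V_c/C + Rv * dV_c/dt`, and the flow obeys
#' `L dQ/dt = P_c - P_down - R Q`.
#'
#' @param Q segment flow, mL/s.
#' @param V_c volume stored in the wall compliance, mL.
#' @param Q_in inflow into the node, mL/s.
#' @param P_down downstream pressure, mmHg.
#' @param seg a [vessel_segment_params()] object.
#' @return A list with `dQ` (mL/s^2), `dV_c` (mL/s) and the node pressure
#'   `P_node` (mmHg).
#' @export
vessel_segment_rhs <- function(Q, V_c, Q_in, P_down, seg) {
  stopifnot(inherits(seg, "vessel_segment_params"))
  dV_c <- Q_in - Q
  P_node <- V_c / seg$C + seg$Rv * dV_c
  dQ <- (P_node - P_down - seg$R * Q) / seg$L
  list(dQ = dQ, dV_c = dV_c, P_node = P_node)
}

#' Windkessel state derivative and terminal pressure
#'
#' The inflow splits between the peripheral resistance (toward `P_out`) and
#' the viscoelastic storage branch. The storage rate and node pressure are
#' obtained by solving the node's flow balance, which is linear in
#' `dV_cwk/dt`.
#'
#' @param V_cwk volume stored in the Windkessel compliance, mL.
#' @param Q_in inflow, mL/s.
#' @param wk a [windkessel_params()] object.
#' @return A list with `dV_cwk` (mL/s), the node pressure `P_node` (mmHg)
#'   and the peripheral outflow `Q_out` (mL/s).
#' @export
windkessel_rhs <- function(V_cwk, Q_in, wk) {
  stopifnot(inherits(wk, "windkessel_params"))
  dV <- (Q_in - (V_cwk / wk$C_wk - wk$P_out) / wk$R_p) /
    (1 + wk$Rv_wk / wk$R_p)
  P_node <- V_cwk / wk$C_wk + wk$Rv_wk * dV
  list(dV_cwk = dV, P_node = P_node,
       Q_out = (P_node - wk$P_out) / wk$R_p)
}
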