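# State vector layout of the coupled model (9 states):
#   V_la, V_lv           chamber volumes (mL)
#   Q_pv                 pulmonary-venous inflow to the LA (mL/s)
#   Q_mv, Q_av           valve flow states (mL/s; regularized diodes)
#   Q_aa                 ascending-aortic segment flow (mL/s)
#   V_cpv, V_caa, V_cwk  volumes stored in the three compliances (mL)

.state_names <- c("V_la", "V_lv", "Q_pv", "Q_mv", "Q_av", "Q_aa",
                  "V_cpv", "V_caa", "V_cwk")
.aux_names <- c("P_la", "P_lv", "P_aa", "P_wk", "E_la", "E_lv",
                "Q_mv_pos", "Q_av_pos", "Q_in", "Q_out")

#' Solver and valve-regularization settings
#'
#' @param points_per_cycle dense output points per cardiac cycle (>= 200 for
#'   reported indices).
#' @param rtol,atol relative/absolute solver tolerances passed to
#'   [deSolve::ode()].
#' @param method integration method; `"lsoda"` switches automatically between
#'   stiff and non-stiff steppers.
#' @param valve_width valve pressure smoothing width, mmHg.
#' @param valve_q_width valve flow smoothing width, mL/s.
#' @param maxsteps maximal internal steps per output interval.
#' @param use_compiled use the compiled right-hand side (the R reference
#'   implementation [system_rhs()] is used when `FALSE`; identical results,
#'   much slower).
#' @return A list of class `simulation_control`.
#' @export
simulation_control <- function(points_per_cycle = 200, rtol = 1e-6,
                               atol = 1e-6, method = "lsoda",
                               valve_width = 0.1, valve_q_width = 1,
                               maxsteps = 50000, use_compiled = TRUE) {
  structure(list(points_per_cycle = as.integer(points_per_cycle),
                 rtol = rtol, atol = atol, method = method,
                 valve_width = valve_width, valve_q_width = valve_q_width,
                 maxsteps = maxsteps, use_compiled = use_compiled),
            class = "simulation_control")
}

#' Precompute derived model quantities
#'
#' Computes the elastance scaling factors and end-systolic times for both
#' chambers and the valve flow coefficients (convective and inertial, in
#' mmHg-mL-s units), and packs everything into the flat parameter vector
#' consumed by the right-hand side.
#'
#' @param ps a `model_parameter_set`.
#' @param control a [simulation_control()] object.
#' @return A list with `parms` (packed vector), `alpha_la`, `alpha_lv`,
#'   `t_max_la`, `t_max_lv` and the valve coefficients.
#' @export
prepare_model <- function(ps, control = simulation_control()) {
  validate_parameter_set(ps)
  v <- ps$values
  T <- v[["T"]]
  la <- .chamber_params(ps, "la")
  lv <- .chamber_params(ps, "lv")
  sc_la <- compute_alpha_scaling(la, T)
  sc_lv <- compute_alpha_scaling(lv, T)

  av <- valve_params(v[["av.EOA"]], v[["av.A_down"]], v[["rho"]])
  elco <- energy_loss_coefficient(av)
  B_av <- v[["rho"]] / (2 * elco^2) * MMHG_PER_DYNE_CM2
  M_av <- 2 * pi * v[["rho"]] / sqrt(2 * elco) * MMHG_PER_DYNE_CM2
  B_mv <- v[["rho"]] / (2 * v[["mv.EOA"]]^2) * MMHG_PER_DYNE_CM2
  M_mv <- v[["mv.M"]]

  block <- function(ch, alpha)
    c(v[[paste0(ch, ".E_max")]], v[[paste0(ch, ".E_min")]],
      v[[paste0(ch, ".R_C")]], v[[paste0(ch, ".R_R")]],
      v[[paste0(ch, ".alpha_S")]], v[[paste0(ch, ".alpha_D")]],
      v[[paste0(ch, ".V_o")]], v[[paste0(ch, ".t_onset")]],
      v[[paste0(ch, ".K")]], v[[paste0(ch, ".P_ext")]], alpha)

  parms <- c(T,
             block("la", sc_la$alpha), block("lv", sc_lv$alpha),
             B_mv, M_mv, B_av, M_av,
             v[["valve.R_closed"]], control$valve_width,
             control$valve_q_width,
             v[["pv.P_src"]], v[["pv.R"]], v[["pv.Rv"]], v[["pv.C"]],
             v[["pv.L"]], v[["pv.V0"]],
             v[["ao.R"]], v[["ao.Rv"]], v[["ao.C"]], v[["ao.L"]],
             v[["wk.R_p"]], v[["wk.C_wk"]], v[["wk.Rv_wk"]], 0)

  list(parms = unname(parms),
       alpha_la = sc_la$alpha, alpha_lv = sc_lv$alpha,
       t_max_la = sc_la$t_max, t_max_lv = sc_lv$t_max,
       B_mv = B_mv, M_mv = M_mv, B_av = B_av, M_av = M_av)
}

#' Coupled right-hand side of the left-heart model (reference implementation)
#'
#' Assembles the chamber pressures (elastance relation plus viscous wall
#' damping), the Double-Hill elastances, the regularized valve laws, the
#' pulmonary-venous and aortic vessel segments and the viscoelastic
#' Windkessel into one coupled derivative. Volume bookkeeping is exact:
#' `d(V_la + V_lv)/dt = Q_pv - Q_av` and total stored volume changes only
#' through the source inflow and the Windkessel outflow.
#'
#' This R implementation is the readable reference; simulation uses an
#' equivalent compiled version, and the two are asserted equal in the test
#' suite.
#'
#' @param t time, s.
#' @param y named state vector (see package vignette for the layout).
#' @param ps a `model_parameter_set`.
#' @param derived output of [prepare_model()]; recomputed when omitted.
#' @param control a [simulation_control()] object.
#' @return A list: derivatives (in state order) and the auxiliary outputs
#'   (pressures, elastances, clamped valve flows, boundary flows).
#' @export
system_rhs <- function(t, y, ps, derived = NULL,
                       control = simulation_control()) {
  if (is.null(derived)) derived <- prepare_model(ps, control)
  p <- derived$parms
  dh <- function(off) {
    # p[off..off+10]: Emax, Emin, Rc, Rr, aS, aD, Vo, onset, K, Pext, alpha
    ep <- elastance_params(p[off + 1], p[off + 2], p[off + 3], p[off + 4],
                           p[off + 5], p[off + 6], max(p[off + 7], 0),
                           p[off + 8])
    double_hill_elastance(t, ep, p[1], p[off + 11])
  }
  V_la <- y[[1]]; V_lv <- y[[2]]; Q_pv <- y[[3]]; Q_mv <- y[[4]]
  Q_av <- y[[5]]; Q_aa <- y[[6]]; V_cpv <- y[[7]]; V_caa <- y[[8]]
  V_cwk <- y[[9]]
  Qmvp <- max(Q_mv, 0); Qavp <- max(Q_av, 0)

  E_la <- dh(1L); E_lv <- dh(12L)
  P_la <- E_la * (V_la - p[8]) + p[10] * (Q_pv - Qmvp) + p[11]
  P_lv <- E_lv * (V_lv - p[19]) + p[21] * (Qmvp - Qavp) + p[22]

  P_src <- p[31]; R_pv <- p[32]; Rv_pv <- p[33]; C_pv <- p[34]
  L_pv <- p[35]; V0_pv <- p[36]
  P_n <- ((V_cpv - V0_pv) / C_pv + Rv_pv * (P_src / R_pv - Q_pv)) /
    (1 + Rv_pv / R_pv)
  Q_src <- (P_src - P_n) / R_pv

  ao_R <- p[37]; ao_Rv <- p[38]; ao_C <- p[39]; ao_L <- p[40]
  P_aa <- V_caa / ao_C + ao_Rv * (Qavp - Q_aa)

  wk <- windkessel_params(p[41], p[42], p[43], p[44])
  wkr <- windkessel_rhs(V_cwk, Q_aa, wk)

  Rcl <- p[28]; w <- p[29]; qw <- p[30]
  s_mv <- valve_state(P_la, P_lv, Q_mv, w, qw)
  s_av <- valve_state(P_lv, P_aa, Q_av, w, qw)

  dy <- c(V_la = Q_pv - Qmvp,
          V_lv = Qmvp - Qavp,
          Q_pv = (P_n - P_la) / L_pv,
          Q_mv = (s_mv * (P_la - P_lv) - p[24] * Qmvp^2 -
                    (1 - s_mv) * Rcl * Q_mv) / p[25],
          Q_av = (s_av * (P_lv - P_aa) - p[26] * Qavp^2 -
                    (1 - s_av) * Rcl * Q_av) / p[27],
          Q_aa = (P_aa - wkr$P_node - ao_R * Q_aa) / ao_L,
          V_cpv = Q_src - Q_pv,
          V_caa = Qavp - Q_aa,
          V_cwk = wkr$dV_cwk)
  if (any(!is.finite(dy)))
    stop("system_rhs: non-finite derivative at t = ", signif(t, 6),
         "; state: ", paste(signif(y, 5), collapse = ", "))
  aux <- c(P_la = P_la, P_lv = P_lv, P_aa = P_aa, P_wk = wkr$P_node,
           E_la = E_la, E_lv = E_lv, Q_mv_pos = Qmvp, Q_av_pos = Qavp,
           Q_in = Q_src, Q_out = wkr$Q_out)
  list(dy, aux)
}

# Physiologic default initial conditions; the steady-state iteration erases
# their influence.
.default_initial_state <- function(ps) {
  v <- ps$values
  c(V_la = 50, V_lv = 120, Q_pv = 0, Q_mv = 0, Q_av = 0, Q_aa = 0,
    V_cpv = v[["pv.V0"]] + v[["pv.C"]] * v[["pv.P_src"]],
    V_caa = v[["ao.C"]] * 75,
    V_cwk = v[["wk.C_wk"]] * 75)
}
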