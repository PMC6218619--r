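.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Integrate one cardiac cycle from state y0 at relative time 0..T.
.integrate_cycle <- function(y0, derived, T, control) {
  times <- seq(0, T, length.out = control$points_per_cycle + 1L)
  if (control$use_compiled) {
    out <- deSolve::ode(y = y0, times = times, func = "cardio_derivs",
                        parms = derived$parms, dllname = "cardioelast",
                        initfunc = "cardio_init", nout = 10L,
                        outnames = .aux_names, method = control$method,
                        rtol = control$rtol, atol = control$atol,
                        maxsteps = control$maxsteps)
  } else {
    ps <- attr(derived, "ps")
    out <- deSolve::ode(y = y0, times = times,
                        func = function(t, y, parms)
                          system_rhs(t, y, ps, derived = derived,
                                     control = control),
                        parms = NULL, method = control$method,
                        rtol = control$rtol, atol = control$atol,
                        maxsteps = control$maxsteps)
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop("integration failed at t = ",
         signif(out[nrow(out), "time"], 6), " (cycle time); state: ",
         paste(signif(out[nrow(out), -1], 5), collapse = ", "))
  out
}

#' Simulate the left-heart model for a fixed number of cycles
#'
#' Integrates the coupled model with a stiff-capable adaptive solver
#' ([deSolve::ode()], lsoda by default) with dense output, restarting the
#' clock each cycle (the elastance drive is periodic). The result is
#' deterministic given identical inputs and settings.
#'
#' @param ps a `model_parameter_set`.
#' @param n_cycles number of cardiac cycles to integrate (>= 1).
#' @param control a [simulation_control()] object.
#' @param y0 optional named initial state; physiologic defaults otherwise.
#' @return An object of class `simulation_result`: a list with `series`
#'   (data frame over all cycles: time, states, pressures, elastances,
#'   clamped valve flows, boundary flows), `T`, `cycles_run`, `converged`
#'   (always `NA` here; see [run_to_periodic_steady_state()]), `derived`
#'   and the parameter set.
#' @export
simulate_model <- function(ps, n_cycles = 10, control = simulation_control(),
                           y0 = NULL) {
  stopifnot(n_cycles >= 1)
  derived <- prepare_model(ps, control)
  attr(derived, "ps") <- ps
  T <- ps$values[["T"]]
  y <- if (is.null(y0)) .default_initial_state(ps) else y0
  pieces <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    out <- .integrate_cycle(y, derived, T, control)
    df <- as.data.frame(out)
    df$time <- df$time + (k - 1) * T
    pieces[[k]] <- if (k == 1) df else df[-1, ]
    y <- out[nrow(out), .state_names]
  }
  series <- do.call(rbind, pieces)
  rownames(series) <- NULL
  structure(list(series = series, T = T, cycles_run = n_cycles,
                 converged = NA, derived = derived, ps = ps,
                 control = control, final_state = y),
            class = "simulation_result")
}

#' Run the model to its periodic steady state
#'
#' Integrates cycle by cycle until consecutive cycles agree: the stroke
#' volume (integral of the aortic-valve flow) and the cycle-mean aortic
#' pressure must both change by less than `tol` (relative), or the start/end
#' states of a cycle must agree to within `tol` in every component
#' (periodicity fixed point). Non-convergence within `max_cycles` is flagged
#' on the result, not raised.
#'
#' @inheritParams simulate_model
#' @param tol relative convergence tolerance.
#' @param max_cycles maximal number of cycles to run.
#' @return A `simulation_result` whose `series` holds the final cycle
#'   re-based to `t` in `[0, T]`, with `converged` and `cycles_run` set.
#' @export
run_to_periodic_steady_state <- function(ps, tol = 1e-3, max_cycles = 30,
                                         control = simulation_control(),
                                         y0 = NULL) {
  stopifnot(tol > 0, max_cycles >= 1)
  derived <- prepare_model(ps, control)
  attr(derived, "ps") <- ps
  T <- ps$values[["T"]]
  y <- if (is.null(y0)) .default_initial_state(ps) else y0
  sv_prev <- NA_real_; pm_prev <- NA_real_
  converged <- FALSE
  out <- NULL
  k <- 0L
  while (k < max_cycles) {
    k <- k + 1L
    out <- .integrate_cycle(y, derived, T, control)
    y_end <- out[nrow(out), .state_names]
    sv <- .trapz(out[, "time"], out[, "Q_av_pos"])
    pm <- mean(out[-nrow(out), "P_aa"])
    state_disc <- max(abs(y_end - y) / (abs(y) + 1))
    metric_ok <- is.finite(sv_prev) &&
      abs(sv - sv_prev) <= tol * max(abs(sv_prev), 1) &&
      abs(pm - pm_prev) <= tol * max(abs(pm_prev), 1)
    if (state_disc <= tol || metric_ok) {
      converged <- TRUE
      break
    }
    sv_prev <- sv; pm_prev <- pm
    y <- y_end
  }
  series <- as.data.frame(out)
  structure(list(series = series, T = T, cycles_run = k,
                 converged = converged, derived = derived, ps = ps,
                 control = control,
                 final_state = out[nrow(out), .state_names],
                 stroke_volume = .trapz(series$time, series$Q_av_pos),
                 mean_aortic_pressure = mean(series$P_aa[-nrow(series)])),
            class = "simulation_result")
}

#' Sampled volumetric flow waveform at a named site
#'
#' @param site one of `"MV"`, `"AV"`, `"AA"`.
#' @param times frame times, s, uniformly spaced in `[0, T)`.
#' @param flow flow values, mL/s.
#' @param T cardiac cycle length, s.
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(site, times, flow, T) {
  site <- match.arg(site, c("MV", "AV", "AA"))
  stopifnot(length(times) == length(flow), length(times) >= 4L, T > 0)
  if (any(times < 0) || any(times >= T))
    stop("flow_waveform: frame times must lie in [0, T)")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-8 * T)
    stop("flow_waveform: frame times must be uniformly spaced")
  structure(list(site = site, times = as.numeric(times),
                 flow = as.numeric(flow), T = T, n_frames = length(times)),
            class = "flow_waveform")
}

# Periodic cubic interpolation of a one-cycle series onto new times.
.periodic_interp <- function(times, values, T, xout) {
  x <- times
  y <- values
  if (abs(x[length(x)] - T) > 1e-9 * T) {
    x <- c(x, T)
    y <- c(y, y[1])
  } else {
    y[length(y)] <- y[1]
  }
  stats::spline(x, y, method = "periodic", xout = xout %% T)$y
}

#' Sample the model flow waveforms on a measurement-like frame grid
#'
#' Interpolates the mitral, aortic-valve and ascending-aorta flows of a
#' converged cycle onto `n_frames` uniform frames over one cycle (periodic
#' cubic interpolation), emulating the frame sampling of time-resolved flow
#' measurements.
#'
#' @param result a `simulation_result` holding one re-based cycle (from
#'   [run_to_periodic_steady_state()]).
#' @param n_frames number of frames per cycle.
#' @return A named list of three [flow_waveform()] objects (`MV`, `AV`,
#'   `AA`).
#' @export
sample_waveforms <- function(result, n_frames = 40) {
  stopifnot(inherits(result, "simulation_result"))
  s <- result$series
  T <- result$T
  frames <- seq(0, T, length.out = n_frames + 1L)[seq_len(n_frames)]
  cols <- c(MV = "Q_mv_pos", AV = "Q_av_pos", AA = "Q_aa")
  out <- lapply(names(cols), function(site)
    flow_waveform(site, frames,
                  .periodic_interp(s$time, s[[cols[[site]]]], T, frames), T))
  names(out) <- names(cols)
  out
}

#' Extract the left-ventricular pressure-volume loop
#'
#' Returns the closed (V, P) curve of the final cycle together with the time
#' of end-systole `t_max` (the maximizer of the ventricular elastance curve)
#' and the end-systolic point interpolated at `t_max`.
#'
#' @param result a `simulation_result` from
#'   [run_to_periodic_steady_state()].
#' @return A list of class `pv_loop`: `V`, `P`, `time`, `t_max`, `V_es`,
#'   `P_es` and the signed loop `area` (mmHg mL, positive counter-clockwise,
#'   i.e. stroke work).
#' @export
extract_pv_loop <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  s <- result$series
  t_max <- result$derived$t_max_lv
  V <- s$V_lv; P <- s$P_lv
  V_es <- stats::approx(s$time, V, xout = t_max)$y
  P_es <- stats::approx(s$time, P, xout = t_max)$y
  n <- length(V)
  # shoelace area; the physiological cycle (filling at low pressure,
  # isovolumic contraction, ejection at high pressure, relaxation) runs
  # counter-clockwise in the (V, P) plane, giving positive stroke work
  area <- 0.5 * sum(V[-n] * P[-1] - V[-1] * P[-n])
  structure(list(V = V, P = P, time = s$time, t_max = t_max,
                 V_es = V_es, P_es = P_es, area = area),
            class = "pv_loop")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Left-heart simulation:", x$cycles_run, "cycle(s), T =",
      signif(x$T, 4), "s\n")
  if (!is.na(x$converged))
    cat("Periodic steady state:",
        if (x$converged) "converged" else "NOT converged", "\n")
  if (!is.null(x$stroke_volume))
    cat(sprintf("SV = %.1f mL, mean aortic pressure = %.1f mmHg\n",
                x$stroke_volume, x$mean_aortic_pressure))
  invisible(x)
}

#' Plot a simulation result
#'
#' Quick base-graphics overview: chamber and aortic pressures, chamber
#' volumes and the three site flows over the simulated time span.
#'
#' @param x a `simulation_result`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.simulation_result <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(s$time, s[, c("P_la", "P_lv", "P_aa")], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "P (mmHg)", ...)
  graphics::legend("topright", c("LA", "LV", "AA"), col = 1:3, lty = 1,
                   bty = "n")
  graphics::matplot(s$time, s[, c("V_la", "V_lv")], type = "l", lty = 1,
                    xlab = "time (s)", ylab = "V (mL)")
  graphics::legend("topright", c("LA", "LV"), col = 1:2, lty = 1, bty = "n")
  graphics::matplot(s$time, s[, c("Q_mv_pos", "Q_av_pos", "Q_aa")],
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "Q (mL/s)")
  graphics::legend("topright", c("MV", "AV", "AA"), col = 1:3, lty = 1,
                   bty = "n")
  invisible(x)
}
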