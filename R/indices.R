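# Derived hemodynamic indices computed from flow waveforms, volumes and cuff
# pressures, mirroring the quantities a stress-MRI study tabulates per
# subject and state.

# Cycle integral of a uniformly sampled periodic waveform: trapezoid with
# periodic closure of the last interval.
.cycle_integral <- function(wf) {
  stopifnot(inherits(wf, "flow_waveform"))
  dt <- wf$T / wf$n_frames
  f <- wf$flow
  sum((f + c(f[-1], f[1])) / 2) * dt
}

#' Stroke volume by integrating the aortic-valve flow waveform
#'
#' Trapezoidal integral of the volumetric flow over the entire cardiac
#' cycle, with periodic closure of the last frame interval.
#'
#' @param av_waveform a [flow_waveform()] covering one full cycle.
#' @return Stroke volume, mL.
#' @export
stroke_volume <- function(av_waveform) {
  sv <- .cycle_integral(av_waveform)
  if (sv < 0) stop("stroke_volume: negative integral - corrupt waveform")
  sv
}

#' Cardiac output
#'
#' `CO = SV * HR / 1000` in L/min.
#'
#' @param SV stroke volume, mL.
#' @param HR heart rate, beats/min.
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(SV, HR) {
  stopifnot(SV >= 0, HR > 0)
  SV * HR / 1000
}

#' Ejection fraction
#'
#' `EF = 100 * SV / EDV` in percent.
#'
#' @param SV stroke volume, mL.
#' @param EDV end-diastolic volume, mL (must exceed `SV`).
#' @return Ejection fraction, %.
#' @export
ejection_fraction <- function(SV, EDV) {
  stopifnot(SV >= 0)
  if (SV > 0 && EDV <= SV)
    stop("ejection_fraction: EDV must exceed SV")
  if (SV == 0) return(0)
  100 * SV / EDV
}

#' Mean arterial pressure from cuff pressures
#'
#' Standard one-third rule: `MAP = DBP + (SBP - DBP) / 3`. Device-reported
#' MAP can be injected instead wherever indices are assembled.
#'
#' @param SBP systolic blood pressure, mmHg.
#' @param DBP diastolic blood pressure, mmHg (must be below `SBP`).
#' @return MAP, mmHg.
#' @export
map_from_cuff <- function(SBP, DBP) {
  if (any(SBP <= DBP)) stop("map_from_cuff: SBP must exceed DBP")
  DBP + (SBP - DBP) / 3
}

#' Systemic vascular resistance
#'
#' `SVR = MAP / CO` with the cardiac output converted to mL/s, giving
#' mmHg s/mL.
#'
#' @param MAP mean arterial pressure, mmHg.
#' @param CO cardiac output, L/min (> 0).
#' @return SVR, mmHg s/mL.
#' @export
svr <- function(MAP, CO) {
  stopifnot(CO > 0)
  MAP / (CO * 1000 / 60)
}

#' Total systemic arterial compliance
#'
#' Ratio of stroke volume to pulse pressure: `CT = SV / (SBP - DBP)`,
#' mL/mmHg.
#'
#' @param SV stroke volume, mL.
#' @param SBP,DBP cuff pressures, mmHg.
#' @return CT, mL/mmHg.
#' @export
total_arterial_compliance <- function(SV, SBP, DBP) {
  if (any(SBP <= DBP))
    stop("total_arterial_compliance: SBP must exceed DBP")
  SV / (SBP - DBP)
}

#' Effective orifice area by the continuity equation
#'
#' `EOA = SV / VTI`: stroke volume divided by the velocity-time integral of
#' the transvalvular flow.
#'
#' @param SV stroke volume, mL.
#' @param VTI velocity-time integral, cm (> 0).
#' @return EOA, cm^2.
#' @export
eoa_continuity <- function(SV, VTI) {
  stopifnot(VTI > 0)
  SV / VTI
}

# Local maxima of a uniformly sampled *periodic* series with a prominence
# filter: the series is treated cyclically (frame n wraps to frame 1), and a
# peak's prominence is its height above the higher of the two deepest
# valleys separating it from the nearest higher point on either side.
.find_peaks <- function(f, prominence) {
  n <- length(f)
  g <- c(f, f, f)                      # cyclic extension, analyze mid copy
  idx <- which(g > c(-Inf, g[-3 * n]) & g >= c(g[-1], -Inf))
  idx <- idx[idx > n & idx <= 2 * n]
  idx <- idx[g[idx] > 0]
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    left <- if (any(g[seq_len(i - 1)] > g[i])) {
      k <- max(which(g[seq_len(i - 1)] > g[i]))
      min(g[k:i])
    } else min(g[seq_len(i)])
    right <- if (any(g[(i + 1):(3 * n)] > g[i])) {
      k <- i + min(which(g[(i + 1):(3 * n)] > g[i]))
      min(g[i:k])
    } else min(g[i:(3 * n)])
    keep[j] <- (g[i] - max(left, right)) >= prominence
  }
  sort(idx[keep] - n)
}

#' Mitral inflow E/A analysis
#'
#' Locates the early-filling (E) and atrial-contraction (A) peaks of the
#' mitral flow waveform: local maxima surviving a prominence threshold
#' (default 5% of the tallest peak, rejecting sampling ripple). The first
#' surviving peak in time is E, the last distinct one is A. When only one
#' local maximum survives the waveform is flagged as merged (E and A waves
#' fuse at high heart rates) and the E/A ratio is undefined.
#'
#' @param mv_waveform a [flow_waveform()] of mitral inflow.
#' @param prominence_frac prominence threshold as a fraction of the tallest
#'   peak.
#' @return A list: `E_peak`, `A_peak` (mL/s; `A_peak` is `NA` when merged),
#'   `E_over_A` (`NA` when merged), `merged` flag, and the peak times.
#' @export
mitral_ea_analysis <- function(mv_waveform, prominence_frac = 0.05) {
  stopifnot(inherits(mv_waveform, "flow_waveform"))
  f <- mv_waveform$flow
  if (all(f <= 0)) stop("mitral_ea_analysis: no positive mitral flow")
  peaks <- .find_peaks(f, prominence_frac * max(f))
  if (length(peaks) == 0L) peaks <- which.max(f)
  if (length(peaks) == 1L) {
    return(list(E_peak = f[peaks], A_peak = NA_real_, E_over_A = NA_real_,
                merged = TRUE, t_E = mv_waveform$times[peaks],
                t_A = NA_real_))
  }
  iE <- peaks[1]; iA <- peaks[length(peaks)]
  list(E_peak = f[iE], A_peak = f[iA], E_over_A = f[iE] / f[iA],
       merged = FALSE, t_E = mv_waveform$times[iE],
       t_A = mv_waveform$times[iA])
}

#' Diastolic fraction of the cardiac cycle
#'
#' Percentage of the cycle spent in diastole, based on the time of
#' end-systole `t_max` from the elastance curve: `100 (T - t_max) / T`.
#'
#' @param t_max time of end-systole, s (in `(0, T)`).
#' @param T cycle length, s.
#' @return Diastolic fraction, %.
#' @export
diastolic_fraction <- function(t_max, T) {
  stopifnot(t_max > 0, t_max < T)
  100 * (T - t_max) / T
}

#' RMSE between a measured and a modeled flow waveform
#'
#' Root mean square error over the measurement frames; the modeled waveform
#' is resampled onto the measured frame times (periodic cubic interpolation)
#' when the grids differ.
#'
#' @param measured,modeled [flow_waveform()] objects at the same site.
#' @return RMSE, mL/s.
#' @export
waveform_rmse <- function(measured, modeled) {
  stopifnot(inherits(measured, "flow_waveform"),
            inherits(modeled, "flow_waveform"))
  if (measured$site != modeled$site)
    stop("waveform_rmse: site mismatch (", measured$site, " vs ",
         modeled$site, ")")
  if (modeled$n_frames == measured$n_frames &&
      max(abs(modeled$times - measured$times)) < 1e-9) {
    m <- modeled$flow
  } else {
    m <- .periodic_interp(modeled$times, modeled$flow, modeled$T,
                          measured$times)
  }
  sqrt(mean((measured$flow - m)^2))
}

#' Assemble the per-subject index row
#'
#' Computes every derived index for one subject/state from a measurement
#' bundle, optionally adding the elastance-derived quantities (time
#' constants, diastolic fraction) from a fitted parameter set.
#'
#' @param m a [subject_measurements()] bundle.
#' @param ps optional fitted `model_parameter_set` supplying `alpha_S`,
#'   `alpha_D` and the end-systolic time of the ventricle.
#' @param map_formula how to obtain MAP: `"device"` uses the measured MAP
#'   when present, falling back to the cuff one-third rule.
#' @return A one-row data frame of indices (HR, SV, CO, EF, MAP, PP, SVR,
#'   CT, EOA, E/A quantities, and when `ps` is given: tau_S, tau_D,
#'   diastolic fraction).
#' @export
compute_indices <- function(m, ps = NULL,
                            map_formula = c("device", "cuff")) {
  stopifnot(inherits(m, "subject_measurements"))
  map_formula <- match.arg(map_formula)
  HR <- 60 / m$T
  SV <- stroke_volume(m$waveforms$AV)
  CO <- cardiac_output(SV, HR)
  EDV <- m$LVESV + SV
  EF <- ejection_fraction(SV, EDV)
  MAP <- if (map_formula == "device" && !is.null(m$MAP) && !is.na(m$MAP))
    m$MAP else map_from_cuff(m$SBP, m$DBP)
  ea <- mitral_ea_analysis(m$waveforms$MV)
  out <- data.frame(
    HR = HR, SV = SV, CO = CO, EDV = EDV, ESV = m$LVESV, EF = EF,
    SBP = m$SBP, DBP = m$DBP, MAP = MAP, PP = m$SBP - m$DBP,
    SVR = svr(MAP, CO),
    CT = total_arterial_compliance(SV, m$SBP, m$DBP),
    EOA = eoa_continuity(SV, m$VTI), VTI = m$VTI,
    E_peak = ea$E_peak, A_peak = ea$A_peak, E_over_A = ea$E_over_A,
    EA_merged = ea$merged)
  if (!is.null(ps)) {
    stopifnot(inherits(ps, "model_parameter_set"))
    tau <- tau_constants(ps$values[["lv.alpha_S"]],
                         ps$values[["lv.alpha_D"]], ps$values[["T"]])
    lv <- .chamber_params(ps, "lv")
    sc <- compute_alpha_scaling(lv, ps$values[["T"]])
    out$tau_S <- tau[["tau_S"]]
    out$tau_D <- tau[["tau_D"]]
    out$t_max <- sc$t_max
    out$diastolic_fraction <- diastolic_fraction(sc$t_max, ps$values[["T"]])
  }
  out
}
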