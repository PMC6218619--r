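#' Time-varying elastance parameters for one heart chamber
#'
#' Bundles the parameters of the Double-Hill elastance curve that describes
#' the contraction and relaxation pattern of a heart chamber over one cardiac
#' cycle: the curve rises from the passive (minimal) elastance `E_min` to the
#' end-systolic (maximal) elastance `E_max` with contraction-rate exponent
#' `R_C`, and relaxes with relaxation-rate exponent `R_R`; the dimensionless
#' shape parameters `alpha_S` and `alpha_D` set the systolic and diastolic
#' time constants relative to the cycle length (`tau_S = alpha_S * T`,
#' `tau_D = alpha_D * T`) and thereby the time of end-systole.
#'
#' @param E_max maximal (end-systolic) elastance, mmHg/mL.
#' @param E_min minimal (passive) elastance, mmHg/mL; must be below `E_max`.
#' @param R_C contraction-rate exponent (dimensionless, > 0).
#' @param R_R relaxation-rate exponent (dimensionless, > 0).
#' @param alpha_S systolic time-constant shape parameter, in (0, 1).
#' @param alpha_D diastolic time-constant shape parameter, in (0, 1).
#' @param V_o unstressed volume, mL (volume-axis intercept of the
#'   pressure-volume relationship).
#' @param t_onset activation-time offset within the cycle, s; 0 for the
#'   ventricle, late-diastolic for the atrium.
#' @return An object of class `elastance_params`.
#' @seealso [double_hill_elastance()], [compute_alpha_scaling()]
#' @export
elastance_params <- function(E_max, E_min, R_C, R_R, alpha_S, alpha_D,
                             V_o = 10, t_onset = 0) {
  p <- list(E_max = E_max, E_min = E_min, R_C = R_C, R_R = R_R,
            alpha_S = alpha_S, alpha_D = alpha_D, V_o = V_o,
            t_onset = t_onset)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("elastance_params: '", nm, "' must be a finite scalar")
  }
  if (!(E_max > E_min && E_min > 0))
    stop("elastance_params: need E_max > E_min > 0")
  if (R_C <= 0 || R_R <= 0)
    stop("elastance_params: rate exponents must be positive")
  if (alpha_S <= 0 || alpha_S >= 1 || alpha_D <= 0 || alpha_D >= 1)
    stop("elastance_params: alpha_S and alpha_D must lie in (0, 1)")
  if (V_o < 0) stop("elastance_params: V_o must be non-negative")
  if (t_onset < 0) stop("elastance_params: t_onset must be non-negative")
  structure(p, class = "elastance_params")
}

# Unscaled product of the two Hill factors, evaluated in log space so that
# large exponents (R_R can exceed 50) cannot overflow: each factor is a
# bounded rational of the form 1 / (1 + exp(e)).
.double_hill_shape <- function(t, p, T) {
  tt <- (t - p$t_onset) %% T
  x <- tt / (p$alpha_S * T)
  y <- tt / (p$alpha_D * T)
  h1 <- ifelse(tt <= 0, 0, 1 / (1 + exp(pmin(-p$R_C * log(x), 700))))
  h2 <- ifelse(tt <= 0, 1, 1 / (1 + exp(pmin(p$R_R * log(y), 700))))
  h1 * h2
}

#' Double-Hill time-varying elastance
#'
#' Evaluates the chamber elastance
#' \deqn{E(t) = \alpha (E_{max}-E_{min})
#'       \frac{x^{R_C}}{1+x^{R_C}} \frac{1}{1+y^{R_R}} + E_{min}}
#' with \eqn{x = t/(\alpha_S T)} and \eqn{y = t/(\alpha_D T)}. Time is taken
#' modulo the cycle length after subtracting the activation offset, so the
#' curve is periodic with period `T`. With the correct scaling factor `alpha`
#' (see [compute_alpha_scaling()]) the curve attains exactly `E_max` at the
#' time of end-systole and equals `E_min` at the activation onset.
#'
#' The Hill factors are evaluated as bounded rationals in log space, so the
#' result is finite for arbitrarily large rate exponents.
#'
#' @param t time, s (vectorized; any non-negative value, wrapped into the
#'   cycle).
#' @param p an [elastance_params()] object.
#' @param T cardiac cycle length, s.
#' @param alpha scaling factor ensuring `max E(t) = E_max`; obtain it from
#'   [compute_alpha_scaling()].
#' @return Elastance, mmHg/mL, same length as `t`.
#' @export
double_hill_elastance <- function(t, p, T, alpha) {
  stopifnot(inherits(p, "elastance_params"), T > 0, alpha > 0)
  e <- alpha * (p$E_max - p$E_min) * .double_hill_shape(t, p, T) + p$E_min
  if (any(!is.finite(e)))
    stop("double_hill_elastance: non-finite elastance value")
  e
}

#' Scaling factor of the Double-Hill elastance curve
#'
#' The raw product of the two Hill factors peaks below 1; the scaling factor
#' `alpha` is its reciprocal peak value, so that the scaled curve attains
#' exactly `E_max`. The maximizing time is the time of end-systole `t_max`,
#' which also defines the diastolic fraction of the cycle (see
#' [diastolic_fraction()]).
#'
#' The peak is located by a coarse grid scan followed by local refinement
#' with [stats::optimize()] to a relative tolerance well below 1e-8.
#'
#' @inheritParams double_hill_elastance
#' @return A list with `alpha` (dimensionless) and `t_max` (s, measured from
#'   the activation onset).
#' @export
compute_alpha_scaling <- function(p, T) {
  stopifnot(inherits(p, "elastance_params"), T > 0)
  p0 <- p
  p0$t_onset <- 0
  grid <- seq(0, T, length.out = 2049L)[-1]
  s <- .double_hill_shape(grid, p0, T)
  i <- which.max(s)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(t) .double_hill_shape(t, p0, T),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * T)
  peak <- max(opt$objective, s[i])
  if (!is.finite(peak) || peak <= 0)
    stop("compute_alpha_scaling: degenerate shape parameters, no maximum")
  t_max <- if (opt$objective >= s[i]) opt$maximum else grid[i]
  list(alpha = 1 / peak, t_max = t_max)
}

#' Chamber pressure from the elastance relation
#'
#' `P = E * (V - V_o)`: the instantaneous chamber pressure given the current
#' elastance and volume. The pressure may be transiently negative when the
#' volume falls below the unstressed volume.
#'
#' @param V chamber volume, mL.
#' @param E instantaneous elastance, mmHg/mL (> 0).
#' @param V_o unstressed volume, mL.
#' @return Pressure, mmHg.
#' @export
chamber_pressure <- function(V, E, V_o) {
  stopifnot(all(E > 0))
  E * (V - V_o)
}

#' Systolic and diastolic elastance time constants
#'
#' `tau_S = alpha_S * T` and `tau_D = alpha_D * T`: the absolute time
#' constants of the systolic rise and diastolic decay of the elastance curve.
#'
#' @param alpha_S systolic time-constant shape parameter.
#' @param alpha_D diastolic time-constant shape parameter.
#' @param T cardiac cycle length, s.
#' @return Named numeric vector with `tau_S` and `tau_D`, s.
#' @export
tau_constants <- function(alpha_S, alpha_D, T) {
  stopifnot(alpha_S >= 0, alpha_D >= 0, T > 0)
  c(tau_S = alpha_S * T, tau_D = alpha_D * T)
}
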