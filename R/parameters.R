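# The full model comprises exactly 40 scalar parameters: 2 global (T, rho),
# 20 chamber parameters (10 per chamber), 5 valve parameters, 6 pulmonary
# venous parameters and 7 systemic vessel parameters. 23 are subject-specific
# (3 assigned directly from measurements: T, aortic EOA, aortic area; 20
# estimated by nonlinear optimization); the remaining 17 are literature-tier
# physiologic defaults. The Windkessel outflow pressure is fixed at 0 mmHg
# and is not counted as a parameter.

.param_table <- function() {
  tab <- rbind(
    # name            default    lower     upper     provenance  units
    c("T",            60 / 66,   0.3,      2.0,      "direct",    "s"),
    c("rho",          1.06,      0.9,      1.2,      "literature","g/mL"),
    c("la.E_max",     0.25,      0.05,     1.5,      "optimized", "mmHg/mL"),
    c("la.E_min",     0.10,      0.02,     0.5,      "optimized", "mmHg/mL"),
    c("la.R_C",       2.0,       0.5,      8.0,      "optimized", "1"),
    c("la.R_R",       20,        4,        120,      "optimized", "1"),
    c("la.alpha_S",   0.07,      0.02,     0.30,     "optimized", "1"),
    c("la.alpha_D",   0.12,      0.04,     0.45,     "optimized", "1"),
    c("la.V_o",       10,        0,        40,       "literature","mL"),
    c("la.t_onset",   0.85 * 60 / 66, 0,   2.0,      "literature","s"),
    c("la.K",         5e-4,      0,        5e-2,     "literature","mmHg s/mL"),
    c("la.P_ext",     0,         -5,       5,        "literature","mmHg"),
    c("lv.E_max",     1.8,       0.3,      18,       "optimized", "mmHg/mL"),
    c("lv.E_min",     0.07,      0.015,    0.4,      "optimized", "mmHg/mL"),
    c("lv.R_C",       1.5,       0.5,      8.0,      "optimized", "1"),
    c("lv.R_R",       37.2,      8,        150,      "optimized", "1"),
    c("lv.alpha_S",   0.30,      0.10,     0.60,     "optimized", "1"),
    c("lv.alpha_D",   0.40,      0.15,     0.80,     "optimized", "1"),
    c("lv.V_o",       10,        0,        40,       "literature","mL"),
    c("lv.t_onset",   0,         0,        0,        "literature","s"),
    c("lv.K",         5e-4,      0,        5e-2,     "literature","mmHg s/mL"),
    c("lv.P_ext",     0,         -5,       5,        "literature","mmHg"),
    c("mv.EOA",       4.0,       1.0,      8.0,      "optimized", "cm^2"),
    c("mv.M",         1.8e-3,    1e-4,     1e-2,     "literature","mmHg s^2/mL"),
    c("av.EOA",       3.5,       0.8,      6.5,      "direct",    "cm^2"),
    c("av.A_down",    7.0,       3.0,      12.0,     "direct",    "cm^2"),
    c("valve.R_closed", 20,      1,        200,      "literature","mmHg s/mL"),
    c("pv.P_src",     10,        4,        25,       "optimized", "mmHg"),
    c("pv.R",         0.03,      0.003,    0.3,      "literature","mmHg s/mL"),
    c("pv.Rv",        0.01,      0.001,    0.1,      "literature","mmHg s/mL"),
    c("pv.C",         4.0,       0.4,      40,       "literature","mL/mmHg"),
    c("pv.L",         5e-5,      5e-6,     5e-4,     "literature","mmHg s^2/mL"),
    c("pv.V0",        10,        0,        100,      "literature","mL"),
    c("ao.R",         0.03,      0.003,    0.3,      "optimized", "mmHg s/mL"),
    c("ao.Rv",        0.01,      0.001,    0.1,      "literature","mmHg s/mL"),
    c("ao.C",         0.11,      0.011,    1.1,      "optimized", "mL/mmHg"),
    c("ao.L",         5e-4,      5e-5,     5e-3,     "optimized", "mmHg s^2/mL"),
    c("wk.R_p",       0.90,      0.2,      3.0,      "optimized", "mmHg s/mL"),
    c("wk.C_wk",      1.8,       0.3,      6.0,      "optimized", "mL/mmHg"),
    c("wk.Rv_wk",     0.05,      0.005,    0.5,      "optimized", "mmHg s/mL")
  )
  data.frame(name = tab[, 1],
             default = as.numeric(tab[, 2]),
             lower = as.numeric(tab[, 3]),
             upper = as.numeric(tab[, 4]),
             provenance = tab[, 5],
             units = tab[, 6],
             stringsAsFactors = FALSE)
}

#' Model parameter table
#'
#' The 40 scalar parameters of the left-heart model with their physiologic
#' default values, optimization/truncation bounds, provenance tier
#' (`literature`, `direct` or `optimized`) and units. Dotted prefixes group
#' the parameters: `la.`/`lv.` chambers, `mv.`/`av.` valves, `pv.` pulmonary
#' venous compartment, `ao.` ascending aortic segment, `wk.` Windkessel.
#'
#' @return A data frame with columns `name`, `default`, `lower`, `upper`,
#'   `provenance`, `units` (40 rows).
#' @export
param_table <- function() .param_table()

#' Names of the parameters estimated by nonlinear optimization
#'
#' The default set of 20 parameters adjusted by the optimizer: the 12
#' chamber shape/stiffness parameters (E_max, E_min, R_C, R_R, alpha_S,
#' alpha_D for atrium and ventricle), the mitral EOA, the aortic segment
#' R/C/L, the Windkessel R_p/C_wk/Rv_wk and the pulmonary source pressure.
#'
#' @return Character vector of length 20.
#' @export
optimized_parameter_names <- function() {
  tab <- .param_table()
  tab$name[tab$provenance == "optimized"]
}

#' Construct the default model parameter set
#'
#' Builds a `model_parameter_set`: a named vector of the 40 model parameters
#' initialized at the literature-tier defaults, with per-parameter provenance
#' flags. The cycle length may be overridden; the atrial activation onset is
#' then placed at 0.85 T (atrial contraction in late diastole).
#'
#' @param T cardiac cycle length, s.
#' @param values optional named numeric vector of overrides (names as in
#'   [param_table()]).
#' @return An object of class `model_parameter_set`.
#' @export
default_parameter_set <- function(T = 60 / 66, values = NULL) {
  tab <- .param_table()
  v <- stats::setNames(tab$default, tab$name)
  v["T"] <- T
  v["la.t_onset"] <- 0.85 * T
  if (!is.null(values)) {
    bad <- setdiff(names(values), tab$name)
    if (length(bad))
      stop("default_parameter_set: unknown parameter(s): ",
           paste(bad, collapse = ", "))
    v[names(values)] <- values
    if ("T" %in% names(values) && !("la.t_onset" %in% names(values)))
      v["la.t_onset"] <- 0.85 * v[["T"]]
  }
  ps <- structure(list(values = v,
                       provenance = stats::setNames(tab$provenance, tab$name)),
                  class = "model_parameter_set")
  validate_parameter_set(ps)
  ps
}

#' Validate a model parameter set
#'
#' Checks the structural invariants: exactly 40 finite scalars, provenance
#' partition 17 literature / 23 subject-specific (of which 20 optimized),
#' chamber elastance orderings, valve areas and positivity of the vessel
#' elements.
#'
#' @param ps a `model_parameter_set`.
#' @return `ps`, invisibly; errors on violation.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "model_parameter_set"))
  v <- ps$values
  tab <- .param_table()
  if (length(v) != 40L || !setequal(names(v), tab$name))
    stop("parameter set must contain exactly the 40 model parameters")
  if (any(!is.finite(v))) stop("non-finite parameter value")
  prov <- table(factor(ps$provenance,
                       levels = c("literature", "direct", "optimized")))
  if (prov[["literature"]] != 17L || prov[["direct"]] != 3L ||
      prov[["optimized"]] != 20L)
    stop("provenance partition must be 17 literature / 3 direct / 20 optimized")
  for (ch in c("la", "lv")) {
    # constructor re-checks the chamber invariants
    elastance_params(v[[paste0(ch, ".E_max")]], v[[paste0(ch, ".E_min")]],
                     v[[paste0(ch, ".R_C")]], v[[paste0(ch, ".R_R")]],
                     v[[paste0(ch, ".alpha_S")]], v[[paste0(ch, ".alpha_D")]],
                     v[[paste0(ch, ".V_o")]], v[[paste0(ch, ".t_onset")]])
  }
  if (v[["av.EOA"]] >= v[["av.A_down"]])
    stop("aortic valve EOA must be below the aortic cross-sectional area")
  pos <- c("T", "rho", "mv.EOA", "mv.M", "valve.R_closed",
           "pv.R", "pv.Rv", "pv.C", "pv.L",
           "ao.R", "ao.Rv", "ao.C", "ao.L",
           "wk.R_p", "wk.C_wk", "wk.Rv_wk")
  if (any(v[pos] <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(pos[v[pos] <= 0], collapse = ", "))
  invisible(ps)
}

#' Update parameters in a parameter set
#'
#' @param ps a `model_parameter_set`.
#' @param values named numeric vector of new values.
#' @param provenance optional provenance flag to record for the updated
#'   parameters (e.g. `"direct"` after assignment from measurements).
#' @return The updated, validated parameter set.
#' @export
set_parameters <- function(ps, values, provenance = NULL) {
  stopifnot(inherits(ps, "model_parameter_set"))
  bad <- setdiff(names(values), names(ps$values))
  if (length(bad))
    stop("set_parameters: unknown parameter(s): ", paste(bad, collapse = ", "))
  ps$values[names(values)] <- values
  if (!is.null(provenance))
    ps$provenance[names(values)] <- provenance
  validate_parameter_set(ps)
  ps
}

# Chamber sub-objects used by the R reference right-hand side.
.chamber_params <- function(ps, ch) {
  v <- ps$values
  elastance_params(v[[paste0(ch, ".E_max")]], v[[paste0(ch, ".E_min")]],
                   v[[paste0(ch, ".R_C")]], v[[paste0(ch, ".R_R")]],
                   v[[paste0(ch, ".alpha_S")]], v[[paste0(ch, ".alpha_D")]],
                   v[[paste0(ch, ".V_o")]], v[[paste0(ch, ".t_onset")]])
}

#' @export
print.model_parameter_set <- function(x, ...) {
  tab <- .param_table()
  cat("Left-heart model parameter set (40 parameters)\n")
  df <- data.frame(name = names(x$values),
                   value = signif(unname(x$values), 5),
                   units = tab$units[match(names(x$values), tab$name)],
                   provenance = unname(x$provenance))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a parameter set to JSON
#'
#' Writes a flat JSON array with one record per parameter (`name`, `value`,
#' `units`, `provenance`), losslessly round-trippable with
#' [read_parameter_set()].
#'
#' @param ps a `model_parameter_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  validate_parameter_set(ps)
  tab <- .param_table()
  df <- data.frame(name = names(ps$values),
                   value = unname(ps$values),
                   units = tab$units[match(names(ps$values), tab$name)],
                   provenance = unname(ps$provenance))
  jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path file written by [write_parameter_set()].
#' @return A `model_parameter_set`.
#' @export
read_parameter_set <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (!all(c("name", "value", "provenance") %in% names(df)))
    stop("read_parameter_set: malformed file, expected name/value/provenance")
  ps <- structure(list(values = stats::setNames(df$value, df$name),
                       provenance = stats::setNames(df$provenance, df$name)),
                  class = "model_parameter_set")
  validate_parameter_set(ps)
  ps
}
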