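# Synthetic paired rest/stress cohort: a stand-in for the study's MRI data.
# Ground-truth parameter sets are drawn around the published cohort centers
# (heart rate, LV elastance parameters, vascular load) with truncated-normal
# marginals and a shared subject-level random effect; measurements are
# forward-simulated and corrupted with frame noise, cuff noise and
# volumetric noise.

.default_regime_table <- function() {
  tab <- rbind(
    # param        rest_mean rest_sd stress_mean stress_sd level
    c("HR",          66,      9,      105,        19,       "regime"),
    c("lv.E_max",    1.8,     0.5,    4.7,        3.6,      "regime"),
    c("lv.E_min",    0.07,    0.02,   0.07,       0.02,     "regime"),
    c("lv.R_C",      1.5,     0.3,    2.0,        0.5,      "regime"),
    c("lv.R_R",      37.2,    6.9,    46.1,       12,       "regime"),
    c("lv.alpha_S",  0.30,    0.03,   0.30,       0.04,     "regime"),
    c("lv.alpha_D",  0.40,    0.05,   0.50,       0.05,     "regime"),
    c("la.E_max",    0.25,    0.05,   0.35,       0.08,     "regime"),
    c("wk.R_p",      0.90,    0.20,   0.60,       0.13,     "regime"),
    c("wk.C_wk",     1.80,    0.45,   2.00,       0.40,     "regime"),
    c("ao.C",        0.11,    0.06,   0.16,       0.10,     "regime"),
    c("pv.P_src",    10,      1.0,    13,         1.5,      "regime"),
    c("mv.EOA",      4.0,     0.4,    4.0,        0.4,      "subject"),
    c("av.EOA",      3.5,     0.35,   3.5,        0.35,     "subject"),
    c("av.A_down",   7.0,     0.7,    7.0,        0.7,      "subject")
  )
  data.frame(param = tab[, 1],
             rest_mean = as.numeric(tab[, 2]),
             rest_sd = as.numeric(tab[, 3]),
             stress_mean = as.numeric(tab[, 4]),
             stress_sd = as.numeric(tab[, 5]),
             level = tab[, 6], stringsAsFactors = FALSE)
}

.param_bounds <- function(param) {
  if (param == "HR") return(c(40, 180))
  tab <- .param_table()
  i <- match(param, tab$name)
  if (is.na(i)) stop("unknown varying parameter: ", param)
  c(tab$lower[i], tab$upper[i])
}

#' Specification of a synthetic paired rest/stress cohort
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' per-regime means and SDs of the varying parameters (heart rate, LV and LA
#' elastance parameters, vascular load), the waveform/cuff/volume noise
#' magnitudes and the frame count. Each subject appears in both regimes;
#' regimes are correlated through a subject-level random effect with
#' intraclass correlation `icc`.
#'
#' @param n_subjects number of paired subjects.
#' @param seed integer seed; the cohort is a pure function of (spec, seed).
#' @param n_frames frames per sampled waveform.
#' @param noise_sd named vector: waveform noise SD (mL/s) at `rest` and
#'   `stress`.
#' @param cuff_sd cuff pressure noise SD, mmHg.
#' @param esv_sd end-systolic volume noise SD, mL.
#' @param icc intraclass correlation of the subject random effect.
#' @param regimes regime parameter table (see
#'   `cardioelast:::.default_regime_table()` for the layout); rows with
#'   `level == "subject"` are drawn once per subject.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 9, seed = 1L, n_frames = 40,
                        noise_sd = c(rest = 25, stress = 45),
                        cuff_sd = 3, esv_sd = 3, icc = 0.5,
                        regimes = NULL) {
  stopifnot(n_subjects >= 2, n_frames >= 8, all(noise_sd >= 0),
            cuff_sd >= 0, esv_sd >= 0, icc >= 0, icc <= 1)
  if (is.null(regimes)) regimes <- .default_regime_table()
  need <- c("param", "rest_mean", "rest_sd", "stress_mean", "stress_sd",
            "level")
  if (!all(need %in% names(regimes)))
    stop("cohort_spec: regime table must have columns ",
         paste(need, collapse = ", "))
  if (any(regimes$rest_sd < 0) || any(regimes$stress_sd < 0))
    stop("cohort_spec: SDs must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 cuff_sd = cuff_sd, esv_sd = esv_sd, icc = icc,
                 regimes = regimes),
            class = "cohort_spec")
}

# One truncated-normal draw correlated with the subject effect z: redraw the
# regime-specific innovation until the value falls inside the physiologic
# bounds (clamp after 200 tries).
.draw_trunc <- function(mean, sd, bounds, z, icc) {
  if (sd == 0) return(min(max(mean, bounds[1]), bounds[2]))
  for (k in 1:200) {
    x <- mean + sd * (sqrt(icc) * z + sqrt(1 - icc) * stats::rnorm(1))
    if (x >= bounds[1] && x <= bounds[2]) return(x)
  }
  min(max(mean + sd * sqrt(icc) * z, bounds[1]), bounds[2])
}

#' Draw one regime's ground-truth parameter set
#'
#' Draws every varying parameter from a truncated normal centered at the
#' regime mean (truncation at the physiologic optimization bounds);
#' non-varying parameters take the literature-tier defaults. Paired draws
#' share the supplied subject-level effects, so rest and stress values are
#' correlated.
#'
#' @param spec a [cohort_spec()].
#' @param regime `"rest"` or `"stress"`.
#' @param z_subject named vector of subject-level standard-normal effects
#'   (one per varying parameter); drawn fresh when `NULL`.
#' @param subject_values named vector of subject-level (regime-invariant)
#'   parameter values already drawn for this subject; drawn here when
#'   `NULL`.
#' @return A list: `ps` (the `model_parameter_set`), `HR`, `z_subject`,
#'   `subject_values`.
#' @export
sample_truth_params <- function(spec, regime = c("rest", "stress"),
                                z_subject = NULL, subject_values = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  regime <- match.arg(regime)
  rt <- spec$regimes
  if (is.null(z_subject))
    z_subject <- stats::setNames(stats::rnorm(nrow(rt)), rt$param)
  mcol <- paste0(regime, "_mean"); scol <- paste0(regime, "_sd")

  subj_rows <- rt$level == "subject"
  if (is.null(subject_values)) {
    subject_values <- stats::setNames(numeric(sum(subj_rows)),
                                      rt$param[subj_rows])
    for (p in rt$param[subj_rows]) {
      i <- match(p, rt$param)
      subject_values[[p]] <- .draw_trunc(rt$rest_mean[i], rt$rest_sd[i],
                                         .param_bounds(p), z_subject[[p]],
                                         spec$icc)
    }
    # valve areas must respect EOA < A_down
    if (all(c("av.EOA", "av.A_down") %in% names(subject_values)) &&
        subject_values[["av.EOA"]] >= 0.95 * subject_values[["av.A_down"]])
      subject_values[["av.EOA"]] <- 0.95 * subject_values[["av.A_down"]]
  }

  for (attempt in 1:100) {
    vals <- subject_values
    HR <- NA_real_
    for (p in rt$param[!subj_rows]) {
      i <- match(p, rt$param)
      x <- .draw_trunc(rt[[mcol]][i], rt[[scol]][i], .param_bounds(p),
                       z_subject[[p]], spec$icc)
      if (p == "HR") HR <- x else vals[[p]] <- x
    }
    if (is.na(HR)) HR <- 66
    ps <- try(default_parameter_set(T = 60 / HR, values = vals),
              silent = TRUE)
    if (!inherits(ps, "try-error"))
      return(list(ps = ps, HR = HR, z_subject = z_subject,
                  subject_values = subject_values))
  }
  stop("sample_truth_params: could not draw a valid parameter set")
}

#' Forward-simulate noisy measurements from a ground-truth parameter set
#'
#' Runs the truth model to its periodic steady state, samples the three flow
#' waveforms on the frame grid and adds iid Gaussian frame noise; cuff
#' pressures are read from the simulated aortic pressure extremes plus cuff
#' noise, the end-systolic volume from the simulated ventricular volume
#' minimum plus volumetric noise. The velocity-time integral is defined on
#' the noise-free flow as `VTI = SV_true / EOA_true` (continuity identity),
#' emulating a velocity measurement at the valve center.
#'
#' @param truth a `model_parameter_set`.
#' @param spec a [cohort_spec()].
#' @param regime `"rest"` or `"stress"` (selects the waveform noise SD).
#' @param id,state tags stored on the bundle.
#' @param sim_control solver settings.
#' @return A [subject_measurements()] bundle; the converged truth simulation
#'   is attached as attribute `"sim"`.
#' @export
synthesize_measurements <- function(truth, spec, regime = c("rest", "stress"),
                                    id = NA_character_, state = NULL,
                                    sim_control = simulation_control()) {
  stopifnot(inherits(truth, "model_parameter_set"),
            inherits(spec, "cohort_spec"))
  regime <- match.arg(regime)
  if (is.null(state)) state <- regime
  sim <- run_to_periodic_steady_state(truth, control = sim_control,
                                      max_cycles = 40)
  if (!sim$converged)
    stop("synthesize_measurements: truth simulation did not converge")
  sigma <- unname(spec$noise_sd[[regime]])
  wfs <- sample_waveforms(sim, spec$n_frames)
  # VTI emulates a separate velocity measurement at the valve center on the
  # noise-free flow: v = Q/EOA, integrated over the same frame grid, so the
  # continuity identity EOA = SV/VTI is exact on noise-free bundles
  SV_frames <- stroke_volume(wfs$AV)
  EOA_true <- truth$values[["av.EOA"]]
  for (site in names(wfs))
    wfs[[site]]$flow <- wfs[[site]]$flow +
      stats::rnorm(spec$n_frames, 0, sigma)
  SBP <- max(sim$series$P_aa) + stats::rnorm(1, 0, spec$cuff_sd)
  DBP <- min(sim$series$P_aa) + stats::rnorm(1, 0, spec$cuff_sd)
  if (SBP <= DBP + 5) SBP <- DBP + 5
  LVESV <- max(min(sim$series$V_lv) + stats::rnorm(1, 0, spec$esv_sd),
               truth$values[["lv.V_o"]] + 5)
  MAP <- mean(sim$series$P_aa[-nrow(sim$series)]) +
    stats::rnorm(1, 0, spec$cuff_sd)
  m <- subject_measurements(T = truth$values[["T"]], SBP = SBP, DBP = DBP,
                            LVESV = LVESV,
                            A_ao = truth$values[["av.A_down"]],
                            VTI = SV_frames / EOA_true, waveforms = wfs,
                            MAP = MAP, id = id, state = state)
  attr(m, "sim") <- sim
  m
}

#' Generate a paired rest/stress synthetic cohort
#'
#' Draws `n_subjects` paired ground-truth parameter sets (stress heart rate
#' strictly above the rest heart rate for every subject, matching the
#' universal chronotropic response to dobutamine) and synthesizes noisy
#' measurement bundles for both regimes. The whole cohort is a pure function
#' of the spec and its seed; subjects whose truth simulation fails to
#' converge are redrawn (bounded retries, logged via `message()`).
#'
#' @param spec a [cohort_spec()].
#' @param sim_control solver settings for the truth simulations.
#' @return An object of class `synthetic_cohort`: a list of subjects (each
#'   with `id`, `rest_truth`, `stress_truth`, `rest_measurements`,
#'   `stress_measurements`) plus a `manifest` recording the spec, seed and
#'   a truth parameter table for recovery scoring.
#' @export
generate_cohort <- function(spec, sim_control = simulation_control()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  subjects <- vector("list", spec$n_subjects)
  truth_rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    id <- sprintf("S%02d", i)
    done <- FALSE
    for (attempt in 1:5) {
      rest <- sample_truth_params(spec, "rest")
      stress <- sample_truth_params(spec, "stress",
                                    z_subject = rest$z_subject,
                                    subject_values = rest$subject_values)
      tries <- 0L
      while (stress$HR <= rest$HR && tries < 50L) {
        stress <- sample_truth_params(spec, "stress",
                                      z_subject = rest$z_subject,
                                      subject_values = rest$subject_values)
        tries <- tries + 1L
      }
      if (stress$HR <= rest$HR) next
      mr <- try(synthesize_measurements(rest$ps, spec, "rest", id = id,
                                        sim_control = sim_control),
                silent = TRUE)
      ms <- try(synthesize_measurements(stress$ps, spec, "stress", id = id,
                                        sim_control = sim_control),
                silent = TRUE)
      if (inherits(mr, "try-error") || inherits(ms, "try-error")) {
        message("generate_cohort: redrawing subject ", id,
                " (attempt ", attempt, ")")
        next
      }
      # study condition: dobutamine raised cardiac output in every subject
      co_rest <- stroke_volume(mr$waveforms$AV) * 60 / mr$T
      co_stress <- stroke_volume(ms$waveforms$AV) * 60 / ms$T
      if (co_stress <= co_rest) {
        message("generate_cohort: redrawing subject ", id,
                " (stress CO not above rest, attempt ", attempt, ")")
        next
      }
      subjects[[i]] <- list(id = id, rest_truth = rest$ps,
                            stress_truth = stress$ps,
                            rest_measurements = mr,
                            stress_measurements = ms)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(subject = id, state = "rest",
                   param = names(rest$ps$values),
                   value = unname(rest$ps$values))
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(subject = id, state = "stress",
                   param = names(stress$ps$values),
                   value = unname(stress$ps$values))
      done <- TRUE
      break
    }
    if (!done)
      stop("generate_cohort: subject ", id,
           " failed to generate after 5 attempts")
  }
  manifest <- list(spec = spec, seed = spec$seed,
                   truth = do.call(rbind, truth_rows),
                   generated = "cardioelast synthetic cohort")
  structure(list(subjects = subjects, manifest = manifest),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired rest/stress cohort:", length(x$subjects),
      "subjects, seed", x$manifest$seed, "\n")
  invisible(x)
}
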