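# File formats: JSON for structured bundles (measurements, fits, parameter
# sets), tidy CSV for waveforms and tables, YAML for pipeline configuration.
# All numeric fields round-trip at full precision.

#' Write flow waveforms to tidy CSV
#'
#' Columns: `site`, `frame`, `time_s`, `flow_ml_s`; one row per frame, and
#' a `cycle_s` column carrying the cycle length.
#'
#' @param waveforms a single [flow_waveform()] or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveforms, path) {
  if (inherits(waveforms, "flow_waveform")) waveforms <- list(waveforms)
  df <- do.call(rbind, lapply(waveforms, function(w)
    data.frame(site = w$site, frame = seq_len(w$n_frames),
               time_s = w$times, flow_ml_s = w$flow, cycle_s = w$T)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read flow waveforms from tidy CSV
#'
#' @param path CSV written by [write_waveform_csv()].
#' @return A named list of [flow_waveform()] objects, one per site.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "frame", "time_s", "flow_ml_s", "cycle_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_waveform_csv: malformed file '", path, "', missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$flow_ml_s) || !is.numeric(df$time_s))
    stop("read_waveform_csv: non-numeric flow or time column")
  out <- lapply(split(df, df$site), function(d) {
    d <- d[order(d$frame), ]
    flow_waveform(d$site[1], d$time_s, d$flow_ml_s, d$cycle_s[1])
  })
  out[intersect(c("MV", "AV", "AA"), names(out))]
}

#' Write a measurement bundle to JSON
#'
#' @param m a [subject_measurements()] bundle.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(m, path) {
  stopifnot(inherits(m, "subject_measurements"))
  obj <- list(id = m$id, state = m$state, T = m$T, SBP = m$SBP, DBP = m$DBP,
              LVESV = m$LVESV, A_ao = m$A_ao, VTI = m$VTI, MAP = m$MAP,
              waveforms = lapply(m$waveforms, function(w)
                list(site = w$site, T = w$T, times = w$times,
                     flow = w$flow)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a measurement bundle from JSON
#'
#' @param path JSON written by [write_measurements()].
#' @return A [subject_measurements()] bundle.
#' @export
read_measurements <- function(path) {
  obj <- jsonlite::fromJSON(path)
  need <- c("T", "SBP", "DBP", "LVESV", "A_ao", "VTI", "waveforms")
  missing_fields <- setdiff(need, names(obj))
  if (length(missing_fields))
    stop("read_measurements: malformed file '", path, "', missing field(s) ",
         paste(missing_fields, collapse = ", "))
  wfs <- lapply(obj$waveforms, function(w)
    flow_waveform(w$site, w$times, w$flow, w$T))
  subject_measurements(T = obj$T, SBP = obj$SBP, DBP = obj$DBP,
                       LVESV = obj$LVESV, A_ao = obj$A_ao, VTI = obj$VTI,
                       waveforms = wfs,
                       MAP = if (is.null(obj$MAP)) NA_real_ else obj$MAP,
                       id = if (is.null(obj$id)) NA_character_ else obj$id,
                       state = if (is.null(obj$state)) NA_character_
                               else obj$state)
}

#' Write a fit result to JSON
#'
#' Stores the provenance-tagged parameter table, the per-site RMSE, the
#' objective trace and the convergence diagnostics.
#'
#' @param fit a `fit_result` from [optimize_parameters()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  tab <- .param_table()
  obj <- list(id = fit$id, state = fit$state,
              converged = fit$converged, n_iterations = fit$n_iterations,
              seed = fit$seed, n_starts = fit$n_starts,
              objective = fit$objective,
              rmse = as.list(fit$rmse),
              rss_trace = fit$rss_trace,
              opt_names = fit$opt_names,
              parameters = data.frame(
                name = names(fit$params$values),
                value = unname(fit$params$values),
                units = tab$units[match(names(fit$params$values), tab$name)],
                provenance = unname(fit$params$provenance)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a fit result from JSON
#'
#' @param path JSON written by [write_fit()].
#' @return A `fit_result` (parameter set reconstructed and validated).
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$parameters))
    stop("read_fit: malformed file '", path, "': no parameter table")
  ps <- structure(list(values = stats::setNames(obj$parameters$value,
                                                obj$parameters$name),
                       provenance = stats::setNames(obj$parameters$provenance,
                                                    obj$parameters$name)),
                  class = "model_parameter_set")
  validate_parameter_set(ps)
  structure(list(params = ps, rmse = unlist(obj$rmse),
                 objective = obj$objective, rss_trace = obj$rss_trace,
                 n_iterations = obj$n_iterations, converged = obj$converged,
                 seed = obj$seed, n_starts = obj$n_starts,
                 opt_names = obj$opt_names, id = obj$id, state = obj$state),
            class = "fit_result")
}

#' Pipeline configuration
#'
#' Validated configuration for [run_full_pipeline()]. Unknown keys are
#' rejected.
#'
#' @param n_subjects cohort size.
#' @param seed master seed for cohort generation and optimization.
#' @param n_frames frames per waveform.
#' @param noise_rest,noise_stress waveform noise SDs, mL/s.
#' @param n_starts optimizer multi-starts per subject/state.
#' @param maxiter optimizer iteration cap.
#' @param n_rounds optimizer outer rounds per start.
#' @param stats_method Wilcoxon method.
#' @param steady_tol periodic steady-state tolerance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 9, seed = 1L, n_frames = 40,
                            noise_rest = 25, noise_stress = 45,
                            n_starts = 1L, maxiter = 40L, n_rounds = 6L,
                            stats_method = "asymptotic",
                            steady_tol = 1e-3) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              n_frames = as.integer(n_frames), noise_rest = noise_rest,
              noise_stress = noise_stress, n_starts = as.integer(n_starts),
              maxiter = as.integer(maxiter), n_rounds = as.integer(n_rounds),
              stats_method = match.arg(stats_method,
                                       c("asymptotic", "exact")),
              steady_tol = steady_tol)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; unknown keys are rejected with an error naming
#'   them.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("read_pipeline_config: unknown key(s): ",
         paste(bad, collapse = ", "))
  do.call(pipeline_config, obj)
}

.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: generate (or load) a paired synthetic cohort,
#' personalize every subject in both states, compute the per-subject
#' indices, run the paired rest-vs-stress statistics on indices and fitted
#' parameters, and score parameter recovery against the generator truth.
#' Every artifact is written with provenance (seed, config hash).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param cohort optional pre-generated `synthetic_cohort` (generated from
#'   the config otherwise).
#' @param progress print per-subject progress.
#' @return A list of class `pipeline_result`: `cohort`, `fits`, `indices`
#'   (per subject/state data frame), `summary` (cohort summary table with
#'   p-values), `recovery` (per-parameter relative errors vs truth),
#'   `config`, `config_hash`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                              cohort = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(n_subjects = config$n_subjects, seed = config$seed,
                      n_frames = config$n_frames,
                      noise_sd = c(rest = config$noise_rest,
                                   stress = config$noise_stress))
  if (is.null(cohort)) cohort <- generate_cohort(spec)
  hash <- .config_hash(config)

  fits <- list()
  idx_rows <- list()
  rec_rows <- list()
  for (sub in cohort$subjects) {
    for (state in c("rest", "stress")) {
      m <- sub[[paste0(state, "_measurements")]]
      fit <- personalize_subject(m, seed = config$seed,
                                 n_starts = config$n_starts,
                                 maxiter = config$maxiter,
                                 n_rounds = config$n_rounds,
                                 ss_tol = config$steady_tol)
      key <- paste(sub$id, state, sep = "_")
      fits[[key]] <- fit
      if (progress)
        message(sprintf("%s %s: converged=%s RMSE=%s", sub$id, state,
                        fit$converged,
                        paste(round(fit$rmse, 1), collapse = "/")))
      idx <- compute_indices(m, ps = fit$params)
      idx_rows[[key]] <- cbind(data.frame(subject = sub$id, state = state),
                               idx,
                               data.frame(
                                 lv_E_max = fit$params$values[["lv.E_max"]],
                                 lv_E_min = fit$params$values[["lv.E_min"]],
                                 lv_R_C = fit$params$values[["lv.R_C"]],
                                 lv_R_R = fit$params$values[["lv.R_R"]],
                                 lv_alpha_S = fit$params$values[["lv.alpha_S"]],
                                 lv_alpha_D = fit$params$values[["lv.alpha_D"]],
                                 rmse_mv = fit$rmse[["MV"]],
                                 rmse_av = fit$rmse[["AV"]],
                                 rmse_aa = fit$rmse[["AA"]]))
      truth <- sub[[paste0(state, "_truth")]]
      rel <- (fit$params$values[fit$opt_names] -
                truth$values[fit$opt_names]) /
        truth$values[fit$opt_names]
      rec_rows[[key]] <- data.frame(subject = sub$id, state = state,
                                    param = fit$opt_names,
                                    truth = unname(truth$values[fit$opt_names]),
                                    fitted = unname(
                                      fit$params$values[fit$opt_names]),
                                    rel_error = unname(rel))
    }
  }
  indices <- do.call(rbind, idx_rows)
  rownames(indices) <- NULL
  recovery <- do.call(rbind, rec_rows)
  rownames(recovery) <- NULL

  vars <- c("HR", "CO", "SBP", "DBP", "MAP", "ESV", "EDV", "SV", "EF",
            "SVR", "CT", "E_peak",
            "lv_E_max", "lv_E_min", "lv_R_C", "lv_R_R", "lv_alpha_S",
            "lv_alpha_D", "tau_S", "tau_D", "diastolic_fraction")
  summary_tab <- summarize_cohort(indices, vars,
                                  method = config$stats_method)

  res <- structure(list(cohort = cohort, fits = fits, indices = indices,
                        summary = summary_tab, recovery = recovery,
                        config = config, config_hash = hash),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(indices, config_hash = hash),
                     file.path(out_dir, "indices.csv"), row.names = FALSE)
    utils::write.csv(cbind(summary_tab, config_hash = hash),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(cbind(recovery, config_hash = hash),
                     file.path(out_dir, "recovery.csv"), row.names = FALSE)
    for (key in names(fits))
      write_fit(fits[[key]], file.path(out_dir, paste0("fit_", key,
                                                       ".json")))
    jsonlite::write_json(list(seed = config$seed, config = unclass(config),
                              config_hash = hash,
                              n_subjects = length(cohort$subjects)),
                         file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  res
}
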