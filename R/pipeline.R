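# Run configuration, session serialisation and the staged pipeline tying
# the modules together: simulate -> condition -> fit -> predict -> vitals
# -> evaluate.

#' Default run configuration
#'
#' Every tunable default of the pipeline in one named list: simulation
#' (cohort size, sensor grade, maneuver counts), conditioning (tail
#' window, smoothing kernel, pairing grid), model selection, robust flag,
#' network hyperparameters and the evaluation scheme.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    subjects = 3L,
    sensor_grade = "A",
    n_fvc = 10L,
    tidal_between = 5L,
    tail_s = 0.5,
    kernel = 10L,
    grid_ms = 10,
    model = "root4",
    robust = FALSE,
    mlp_hidden = 7L,
    mlp_max_iter = 1000L,
    mlp_patience = 6L,
    scheme = "inclusive",
    n_folds = 5L
  )
}

#' Validate and resolve a run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param config Named list of overrides (possibly empty).
#' @return The fully resolved configuration.
#' @export
resolve_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(config$sensor_grade) && !config$sensor_grade %in% c("A", "B")) {
    stop("`sensor_grade` must be 'A' or 'B'", call. = FALSE)
  }
  utils::modifyList(defaults, config)
}

#' Write a session's traces and truth labels to a directory
#'
#' One CSV per trace (inside, outside, reference_flow, truth_flow) plus a
#' JSON sidecar with the subject profile, truth vitals and segment labels.
#'
#' @param session A `spiro_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "spiro_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trace(session$inside, file.path(dir, "inside.csv"))
  write_trace(session$outside, file.path(dir, "outside.csv"))
  write_trace(session$reference_flow, file.path(dir, "reference_flow.csv"))
  write_trace(session$truth_flow, file.path(dir, "truth_flow.csv"))
  sidecar <- list(
    profile = unclass(session$profile),
    truth_vitals = lapply(session$truth_vitals, unclass),
    segment_labels = session$segment_labels
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `spiro_session`.
#' @export
read_session <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  profile <- do.call(subject_profile, c(
    sidecar$profile[setdiff(names(sidecar$profile), "pressure_gain")],
    list(pressure_gain = as.list(sidecar$profile$pressure_gain))
  ))
  labels <- as.data.frame(sidecar$segment_labels)
  vit <- sidecar$truth_vitals
  truth_vitals <- lapply(seq_len(nrow(vit)), function(i) {
    do.call(fvc_vitals, as.list(vit[i, ]))
  })
  structure(
    list(inside = read_trace(file.path(dir, "inside.csv")),
         outside = read_trace(file.path(dir, "outside.csv")),
         reference_flow = read_trace(file.path(dir, "reference_flow.csv")),
         truth_flow = read_trace(file.path(dir, "truth_flow.csv")),
         truth_vitals = truth_vitals,
         segment_labels = labels,
         profile = profile),
    class = "spiro_session"
  )
}

#' Run the staged pipeline end to end
#'
#' Simulates (or loads) a cohort, conditions each session, fits the
#' configured calibration model under the configured division scheme,
#' derives vitals from predicted and reference flow, and writes per-stage
#' artifacts: the session CSVs, the fitted model (inclusive refit on all
#' data) as JSON, per-maneuver vitals and the delta report, plus a run log
#' carrying the fully resolved configuration, its hash and the seeds used.
#' Deterministic stages are bit-identical across reruns of the same
#' configuration.
#'
#' @param config Named list of configuration overrides (see
#'   [default_config()]); unknown keys abort before any compute.
#' @param out_dir Output directory.
#' @param sessions Optional pre-built list of `spiro_session`s; when
#'   supplied the simulate stage is skipped.
#' @return The `delta_report`, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config = list(), out_dir, sessions = NULL) {
  cfg <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = cfg,
              config_hash = digest_config(cfg),
              stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    res
  }

  if (is.null(sessions)) {
    sessions <- stage("simulate", {
      profiles <- random_profiles(cfg$subjects, seed = cfg$seed)
      simulate_session(profiles, sensor_spec(cfg$sensor_grade), seed = cfg$seed,
                       n_fvc = cfg$n_fvc, tidal_between = cfg$tidal_between)
    })
    for (i in seq_along(sessions)) {
      write_session(sessions[[i]], file.path(out_dir, sprintf("session%02d", i)))
    }
  }
  log$stages$simulate <- list(subjects = length(sessions),
                              samples = vapply(sessions, function(s) length(s$inside), 0L))

  cond_args <- list(tail_s = cfg$tail_s, kernel = cfg$kernel, grid_ms = cfg$grid_ms)
  spec <- parse_model_spec(cfg$model, robust = cfg$robust)
  scheme <- division_scheme(cfg$scheme, n_folds = cfg$n_folds, seed = cfg$seed)

  report <- stage("evaluate", {
    run_scheme(sessions, scheme, spec, seed = cfg$seed, condition_args = cond_args)
  })

  # inclusive refit on everything for the exported model artifact
  model <- stage("fit", {
    prepared <- lapply(sessions, prepare_session, condition_args = cond_args)
    fit_calibration(lapply(prepared, `[[`, "pair"), spec, seed = cfg$seed)
  })
  write_model(model, file.path(out_dir, "model.json"))

  vitals_out <- stage("vitals", {
    lapply(seq_along(sessions), function(i) {
      pr <- prepare_session(sessions[[i]], cond_args)
      pred_flow <- flow_trace(pr$pair$grid_times, predict(model, pr$pair$dp))
      lapply(seq_len(nrow(pr$fvc_segs)), function(k) {
        list(maneuver = k,
             reference = unclass(pr$ref_vitals[[k]]),
             predicted = unclass(compute_fvc_vitals(pred_flow, as.list(pr$fvc_segs[k, ]))))
      })
    })
  })
  jsonlite::write_json(vitals_out, file.path(out_dir, "vitals.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(scheme = report$scheme, model = report$model_id,
                            delta = as.list(report$delta)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log$stages$fit <- list(model = spec$id, gof_rmse = model$report$rmse_gof)
  log$stages$evaluate <- list(scheme = report$scheme, delta = as.list(report$delta))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

# stable hash of the resolved configuration for provenance logging
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  # small FNV-1a over the serialised config (no extra dependency needed)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
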