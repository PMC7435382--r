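# Agreement evaluation: the range-normalised RMSE metric (delta) between
# reference-instrument and barometer-predicted quantities, and the three
# participant-division calibration schemes.

#' Range-normalised RMSE between paired vital values
#'
#' `delta = rmse(ref - pred) / max(range(ref), range(pred))`: the RMSE of
#' the paired differences divided by the larger of the two instruments'
#' value ranges over all maneuvers in the evaluation set. Dimensionless;
#' invariant to rescaling both lists by the same factor.
#'
#' @param ref,pred Equal-length numeric vectors, or lists of `fvc_vitals`
#'   (then `vital` selects the component).
#' @param vital Vital name (`"fvc"`, `"fev1"`, `"pef"`, `"fef25"`,
#'   `"fif25"`) when `ref`/`pred` are vitals lists.
#' @return The delta value (>= 0).
#' @export
delta_vitals <- function(ref, pred, vital = NULL) {
  pick <- function(v) {
    if (is.numeric(v)) return(as.numeric(v))
    stopifnot(!is.null(vital))
    vapply(v, function(e) as.numeric(e[[vital]]), 0)
  }
  r <- pick(ref)
  p <- pick(pred)
  if (length(r) != length(p)) stop("ref and pred must be paired (equal length)", call. = FALSE)
  if (length(r) < 2L) stop("need at least 2 paired values (range must be defined)", call. = FALSE)
  denom <- max(diff(range(r)), diff(range(p)))
  if (denom == 0) stop("zero range in both lists: delta undefined", call. = FALSE)
  rmse(r - p) / denom
}

#' Range-normalised RMSE between continuous signals
#'
#' The same metric as [delta_vitals()] applied sample-wise to continuous
#' airflow or volume series on a common grid.
#'
#' @param ref,pred Equal-length numeric series.
#' @return The delta value.
#' @export
delta_signal <- function(ref, pred) {
  ref <- as.numeric(ref)
  pred <- as.numeric(pred)
  if (length(ref) != length(pred)) stop("series must share a grid (equal length)", call. = FALSE)
  denom <- max(diff(range(ref)), diff(range(pred)))
  if (denom == 0) stop("zero range in both series: delta undefined", call. = FALSE)
  rmse(ref - pred) / denom
}

#' Participant-division scheme
#'
#' How the cohort is split between calibration fitting and testing:
#' `"individual"` fits one model per subject and tests it on that subject;
#' `"inclusive"` fits a single model on all subjects pooled and tests on
#' all; `"exclusive"` partitions the subjects (never individual samples)
#' into `n_folds` random folds, fits on the other folds and tests on the
#' held-out fold, so the model always faces a stranger.
#'
#' @param kind `"individual"`, `"inclusive"` or `"exclusive"`.
#' @param n_folds Number of subject folds (exclusive only).
#' @param seed Seed for the fold shuffle.
#' @return A `division_scheme` object.
#' @export
division_scheme <- function(kind = c("individual", "inclusive", "exclusive"),
                            n_folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_folds >= 2L)
  structure(list(kind = kind, n_folds = as.integer(n_folds), seed = seed),
            class = "division_scheme")
}

#' Calibration model specification
#'
#' A declarative description of which calibration family to fit;
#' consumed by [run_scheme()] and [run_pipeline()].
#'
#' @param family `"root"`, `"poly"` or `"mlp"`.
#' @param variant Root variant (root family).
#' @param degree Polynomial degree (poly family).
#' @param hidden_units Hidden neurons (mlp family).
#' @param robust Least-absolute-residual refinement (root/poly).
#' @return A `model_spec` object with an `id` string such as `"root4"`,
#'   `"poly5"` or `"ann7"`.
#' @export
model_spec <- function(family = c("root", "poly", "mlp"),
                       variant = "root4", degree = 5, hidden_units = 7,
                       robust = FALSE) {
  family <- match.arg(family)
  id <- switch(family,
               root = variant,
               poly = paste0("poly", degree),
               mlp = paste0("ann", hidden_units))
  structure(list(family = family, variant = variant, degree = degree,
                 hidden_units = hidden_units, robust = robust, id = id),
            class = "model_spec")
}

#' Parse a model id string into a specification
#'
#' Accepts ids like `"root2only"`, `"root4"`, `"poly2"`..`"poly5"`,
#' `"ann1"`, `"ann7"`.
#'
#' @param id Model id string.
#' @param robust Robust flag for root/poly families.
#' @return A [model_spec()].
#' @export
parse_model_spec <- function(id, robust = FALSE) {
  if (id %in% names(ROOT_VARIANTS)) {
    model_spec("root", variant = id, robust = robust)
  } else if (grepl("^poly[2-5]$", id)) {
    model_spec("poly", degree = as.integer(sub("poly", "", id)), robust = robust)
  } else if (grepl("^ann[0-9]+$", id)) {
    model_spec("mlp", hidden_units = as.integer(sub("ann", "", id)))
  } else {
    stop(sprintf("unknown model id '%s'", id), call. = FALSE)
  }
}

# fit any family on pooled conditioned pairs
fit_calibration <- function(pairs, spec, seed = 1L) {
  switch(spec$family,
         root = fit_root(pairs, spec$variant, robust = spec$robust),
         poly = fit_poly(pairs, spec$degree, robust = spec$robust),
         mlp = fit_mlp(pairs, spec$hidden_units, seed = seed))
}

VITAL_NAMES <- c("fev1", "fvc", "pef", "fef25", "fif25")

# Condition one session and precompute everything reused across schemes:
# the conditioned pair, reference vitals per labelled maneuver, and the
# reference sliding-window volume.
prepare_session <- function(session, condition_args = list()) {
  pair <- do.call(make_conditioned_pair,
                  c(list(session$inside, session$outside, session$reference_flow),
                    condition_args))
  ref_flow <- flow_trace(pair$grid_times, pair$flow, label = "reference")
  segs <- session$segment_labels
  fvc_segs <- segs[segs$kind == "fvc", , drop = FALSE]
  ref_vitals <- lapply(seq_len(nrow(fvc_segs)), function(k) {
    compute_fvc_vitals(ref_flow, as.list(fvc_segs[k, ]))
  })
  list(pair = pair, ref_flow = ref_flow, fvc_segs = fvc_segs,
       ref_vitals = ref_vitals, labels = segs)
}

# Predict with one fitted model over a set of prepared sessions and pool
# the paired quantities: reference/predicted vitals per maneuver plus the
# continuous airflow and sliding-window volume series.
unit_predictions <- function(model, prepared) {
  out <- list(ref_vitals = list(), pred_vitals = list(),
              ref_sig = numeric(0), pred_sig = numeric(0),
              ref_vol = numeric(0), pred_vol = numeric(0))
  for (pr in prepared) {
    pred_flow <- flow_trace(pr$pair$grid_times, predict(model, pr$pair$dp),
                            label = "predicted")
    pv <- lapply(seq_len(nrow(pr$fvc_segs)), function(k) {
      compute_fvc_vitals(pred_flow, as.list(pr$fvc_segs[k, ]))
    })
    out$ref_vitals <- c(out$ref_vitals, pr$ref_vitals)
    out$pred_vitals <- c(out$pred_vitals, pv)
    out$ref_sig <- c(out$ref_sig, pr$pair$flow)
    out$pred_sig <- c(out$pred_sig, pred_flow$values)
    out$ref_vol <- c(out$ref_vol, sliding_window_volume(pr$ref_flow)$values)
    out$pred_vol <- c(out$pred_vol, sliding_window_volume(pred_flow)$values)
  }
  out
}

vital_vec <- function(vitals, nm) vapply(vitals, function(e) as.numeric(e[[nm]]), 0)

# delta components for a set of prediction units. Denominator ranges are
# taken over `scope_units` (the whole evaluation set by default, matching
# the metric's "range over all participants"); with fold-local scope each
# unit supplies its own denominator.
unit_deltas <- function(units, scope = c("global", "unit")) {
  scope <- match.arg(scope)
  denom_from <- function(us, field_ref, field_pred, nm = NULL) {
    r <- unlist(lapply(us, function(u) {
      if (is.null(nm)) u[[field_ref]] else vital_vec(u[[field_ref]], nm)
    }))
    p <- unlist(lapply(us, function(u) {
      if (is.null(nm)) u[[field_pred]] else vital_vec(u[[field_pred]], nm)
    }))
    max(diff(range(r)), diff(range(p)))
  }
  t(vapply(seq_along(units), function(i) {
    u <- units[[i]]
    scope_units <- if (scope == "global") units else units[i]
    d <- vapply(VITAL_NAMES, function(nm) {
      denom <- denom_from(scope_units, "ref_vitals", "pred_vitals", nm)
      if (denom == 0) stop("zero vital range: delta undefined", call. = FALSE)
      rmse(vital_vec(u$ref_vitals, nm) - vital_vec(u$pred_vitals, nm)) / denom
    }, 0)
    c(d,
      airflow = rmse(u$ref_sig - u$pred_sig) /
        denom_from(scope_units, "ref_sig", "pred_sig"),
      volume = rmse(u$ref_vol - u$pred_vol) /
        denom_from(scope_units, "ref_vol", "pred_vol"))
  }, numeric(length(VITAL_NAMES) + 2L)))
}

#' Evaluate a calibration scheme on a cohort of sessions
#'
#' Conditions every session, fits the requested calibration model under
#' the division scheme, predicts flow from differential pressure on the
#' held-out data, and reports the agreement deltas for the five FVC vitals
#' plus continuous airflow and sliding-window volume. When a scheme yields
#' multiple models (individual: one per subject; exclusive: one per fold),
#' each component delta is computed within its unit (subject or fold,
#' using the unit-local value range) and the components are aggregated by
#' root mean square.
#'
#' @param sessions List of `spiro_session` objects.
#' @param scheme A [division_scheme()].
#' @param spec A [model_spec()].
#' @param seed Seed for model fitting (MLP split/init).
#' @param condition_args Named list of overrides for
#'   [make_conditioned_pair()] (e.g. `tail_s`, `kernel`, `grid_ms`).
#' @param range_scope Denominator range for the exclusive scheme:
#'   `"fold"` (default) uses each held-out fold's own value range,
#'   `"global"` the range over the whole cohort. Individual and inclusive
#'   schemes always use the cohort-wide range, matching the metric's
#'   definition over all participants.
#' @return A `delta_report`: list with `scheme`, `model_id`, `delta`
#'   (named vector: fev1, fvc, pef, fef25, fif25, airflow, volume) and
#'   `components` (per-subject or per-fold delta matrix).
#' @export
run_scheme <- function(sessions, scheme = division_scheme("inclusive"),
                       spec = model_spec("root", "root4"), seed = 1L,
                       condition_args = list(),
                       range_scope = c("fold", "global")) {
  if (inherits(sessions, "spiro_session")) sessions <- list(sessions)
  stopifnot(inherits(scheme, "division_scheme"), inherits(spec, "model_spec"))
  range_scope <- match.arg(range_scope)
  n <- length(sessions)
  prepared <- lapply(sessions, prepare_session, condition_args = condition_args)
  if (!all(vapply(prepared, function(p) nrow(p$fvc_segs) > 0, TRUE))) {
    stop("every session must contain at least one FVC maneuver", call. = FALSE)
  }

  if (scheme$kind == "inclusive") {
    model <- fit_calibration(lapply(prepared, `[[`, "pair"), spec,
                             seed = child_seed(seed, 1))
    units <- list(all = unit_predictions(model, prepared))
    components <- unit_deltas(units, scope = "global")
    rownames(components) <- "all"
  } else if (scheme$kind == "individual") {
    units <- lapply(seq_len(n), function(i) {
      m <- fit_calibration(prepared[[i]]$pair, spec, seed = child_seed(seed, i))
      unit_predictions(m, prepared[i])
    })
    components <- unit_deltas(units, scope = "global")
    rownames(components) <- paste0("subject", seq_len(n))
  } else {
    if (n < scheme$n_folds) {
      stop(sprintf("exclusive scheme needs at least n_folds = %d subjects (got %d)",
                   scheme$n_folds, n), call. = FALSE)
    }
    folds <- with_seed(scheme$seed, {
      split(sample.int(n), rep_len(seq_len(scheme$n_folds), n))
    })
    units <- lapply(seq_along(folds), function(f) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      m <- fit_calibration(lapply(prepared[train_idx], `[[`, "pair"), spec,
                           seed = child_seed(seed, f))
      unit_predictions(m, prepared[test_idx])
    })
    components <- unit_deltas(units,
                              scope = if (range_scope == "fold") "unit" else "global")
    rownames(components) <- paste0("fold", seq_along(folds))
  }
  delta <- apply(components, 2L, rmse)
  structure(list(scheme = scheme$kind, model_id = spec$id,
                 delta = delta, components = components),
            class = "delta_report")
}

#' @export
print.delta_report <- function(x, ...) {
  cat(sprintf("<delta_report> scheme %s, model %s\n", x$scheme, x$model_id))
  print(round(x$delta, 4))
  invisible(x)
}
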