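# Breath segmentation, volume integration, flow-volume loops and
# forced-vital-capacity vitals from a (measured or predicted) flow signal.

cumtrapz_vec <- function(times, values) {
  as.numeric(pracma::cumtrapz(times, values))
}

# window a trace to [t0, t1]
trace_window <- function(trace, t0, t1) {
  keep <- trace$times >= t0 & trace$times <= t1
  list(times = trace$times[keep], values = trace$values[keep])
}

#' Segment a flow signal into breaths and forced maneuvers
#'
#' Breath boundaries are negative-to-positive zero crossings of the flow
#' (start of an expiration), detected with a hysteresis band of
#' `+/- hysteresis` L/s so that sensor noise below the band cannot create
#' spurious crossings. A segment is classified as a forced (FVC) maneuver
#' when its peak expiratory flow exceeds `fvc_pef_threshold_factor` times
#' the session's median segment peak (the median peak is a tidal peak when
#' maneuvers are a minority). For FVC segments the start is extended back
#' to the preceding positive-to-negative crossing so the maximal
#' inspiration belongs to the maneuver, and `expiratory_onset` records the
#' zero crossing before the flow maximum.
#'
#' @param flow A [flow_trace()] (conditioned: offsets removed).
#' @param fvc_pef_threshold_factor Peak-flow multiple separating forced
#'   maneuvers from tidal breaths.
#' @param hysteresis Crossing hysteresis band in L/s.
#' @return A data.frame with columns `kind` ("tidal"/"fvc"), `start_time`,
#'   `end_time`, `expiratory_onset` (NA for tidal). Empty for all-zero flow.
#' @export
segment_breaths <- function(flow, fvc_pef_threshold_factor = 3.0,
                            hysteresis = 0.05) {
  stopifnot(inherits(flow, "flow_trace"))
  t <- flow$times
  v <- flow$values
  empty <- data.frame(kind = character(0), start_time = numeric(0),
                      end_time = numeric(0), expiratory_onset = numeric(0))
  # hysteresis state machine: state +1 after v > +h, -1 after v < -h; the
  # crossing time is the last non-positive (resp. non-negative) sample
  # before the band was left
  state <- 0L
  up_cross <- numeric(0)    # neg -> pos (expiratory onsets)
  down_cross <- numeric(0)  # pos -> neg (inspiratory onsets)
  for (i in seq_along(v)) {
    if (v[i] > hysteresis && state <= 0L) {
      if (state == -1L) {
        j <- i
        while (j > 1L && v[j] > 0) j <- j - 1L
        up_cross <- c(up_cross, t[j])
      }
      state <- 1L
    } else if (v[i] < -hysteresis && state >= 0L) {
      if (state == 1L) {
        j <- i
        while (j > 1L && v[j] < 0) j <- j - 1L
        down_cross <- c(down_cross, t[j])
      }
      state <- -1L
    }
  }
  if (length(up_cross) < 1L) return(empty)
  bounds <- c(up_cross, t[length(t)])
  seg <- data.frame(start_time = bounds[-length(bounds)],
                    end_time = bounds[-1L])
  seg$peak <- vapply(seq_len(nrow(seg)), function(k) {
    w <- trace_window(flow, seg$start_time[k], seg$end_time[k])
    if (!length(w$values)) 0 else max(w$values)
  }, 0)
  med_peak <- median(seg$peak)
  seg$kind <- ifelse(seg$peak > fvc_pef_threshold_factor * med_peak, "fvc", "tidal")
  seg$expiratory_onset <- NA_real_
  for (k in which(seg$kind == "fvc")) {
    seg$expiratory_onset[k] <- seg$start_time[k]
    prev_down <- down_cross[down_cross < seg$start_time[k]]
    if (length(prev_down)) {
      ins_start <- max(prev_down)
      seg$start_time[k] <- ins_start
      if (k > 1L) seg$end_time[k - 1L] <- ins_start
    }
  }
  seg[, c("kind", "start_time", "end_time", "expiratory_onset")]
}

#' Cumulative expired volume over a segment
#'
#' Trapezoidal integral of the flow from the segment's expiratory onset
#' (or start when no onset is recorded), in liters.
#'
#' @param flow A [flow_trace()].
#' @param segment One row of a segment table (list or single-row
#'   data.frame with `start_time`, `end_time`, optionally
#'   `expiratory_onset`), or `NULL` for the whole trace.
#' @return A `volume_trace` (times in s, values in L).
#' @export
cumulative_volume <- function(flow, segment = NULL) {
  stopifnot(inherits(flow, "flow_trace"))
  if (is.null(segment)) {
    w <- list(times = flow$times, values = flow$values)
    origin <- flow$times[1L]
  } else {
    segment <- as.list(segment)
    w <- trace_window(flow, segment$start_time, segment$end_time)
    if (length(w$times) < 2L) stop("segment lies outside the trace span", call. = FALSE)
    origin <- if (!is.null(segment$expiratory_onset) && is.finite(segment$expiratory_onset)) {
      segment$expiratory_onset
    } else {
      segment$start_time
    }
  }
  vol <- cumtrapz_vec(w$times, w$values)
  # shift so volume is 0 at the integration origin
  v0 <- approx(w$times, vol, xout = origin, rule = 2)$y
  new_trace(w$times, vol - v0, "L", sample_rate = flow$sample_rate,
            label = paste0("volume(", flow$label, ")"))
}

#' Sliding-window air volume
#'
#' The trapezoidal integral of the flow over a trailing window
#' (`[t - window, t]`), emitted every `step` seconds. Windowed integration
#' avoids the drift that accumulates when integrating a long recording in
#' one pass; the default 0.5 s window with a 10 ms step reports tidal
#' volume-scale quantities continuously.
#'
#' @param flow A [flow_trace()].
#' @param window Window length in s.
#' @param step Step between emitted values in s.
#' @return A `volume_trace`; first value at `start + window`.
#' @export
sliding_window_volume <- function(flow, window = 0.5, step = 0.010) {
  stopifnot(inherits(flow, "flow_trace"), window > 0, step > 0)
  if (trace_duration(flow) < window) {
    stop("flow duration must be at least one window length", call. = FALSE)
  }
  grid <- seq(trace_start(flow), trace_end(flow), by = step)
  fg <- trace_interp(flow, grid)
  cum <- cumtrapz_vec(grid, fg)
  out_t <- grid[grid >= trace_start(flow) + window - 1e-12]
  lead <- approx(grid, cum, xout = out_t, rule = 2)$y
  lag <- approx(grid, cum, xout = out_t - window, rule = 2)$y
  new_trace(out_t, lead - lag, "L", sample_rate = 1 / step,
            label = paste0("windowed_volume(", flow$label, ")"))
}

#' Flow-volume loop of a forced maneuver
#'
#' Pairs cumulative expired volume (x axis, zero at the expiratory onset)
#' with instantaneous flow (y axis) over the full maneuver, including the
#' inspiratory limb.
#'
#' @param flow A [flow_trace()].
#' @param segment A segment row with `kind == "fvc"`.
#' @return A `flow_volume_loop`: list with `volume` (L), `flow` (L/s),
#'   `segment`.
#' @export
flow_volume_loop <- function(flow, segment) {
  segment <- as.list(segment)
  if (!identical(segment$kind, "fvc")) {
    stop("flow-volume loops are defined for segments of kind 'fvc'", call. = FALSE)
  }
  w <- trace_window(flow, segment$start_time, segment$end_time)
  if (length(w$times) < 2L || max(abs(w$values)) < 1e-9) {
    stop("degenerate (near-zero-flow) segment: no loop to construct", call. = FALSE)
  }
  vol <- cumtrapz_vec(w$times, w$values)
  onset <- if (is.finite(segment$expiratory_onset)) segment$expiratory_onset else segment$start_time
  v0 <- approx(w$times, vol, xout = onset, rule = 2)$y
  structure(list(volume = vol - v0, flow = w$values, times = w$times,
                 segment = segment),
            class = "flow_volume_loop")
}

#' @export
print.flow_volume_loop <- function(x, ...) {
  cat(sprintf("<flow_volume_loop> %d points, volume 0..%.2f L, peak flow %.2f L/s\n",
              length(x$flow), max(x$volume), max(x$flow)))
  invisible(x)
}

# locate the first time a monotone-sampled cumulative series crosses q,
# linearly interpolating between bracketing samples; returns the
# interpolated companion value from `values`
interp_at_crossing <- function(series, values, q) {
  idx <- which(series >= q)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(values[1L])
  theta <- (q - series[i - 1L]) / (series[i] - series[i - 1L])
  values[i - 1L] + theta * (values[i] - values[i - 1L])
}

#' Forced-vital-capacity vitals of one maneuver
#'
#' Computes the clinical scalars of a forced maneuver from the flow
#' signal:
#' * `fvc` -- total expired volume over the forced expiration;
#' * `pef` -- maximum expiratory flow;
#' * `fev1` -- volume expired in the first second after the
#'   back-extrapolated time zero (the tangent at the steepest point of the
#'   volume curve, i.e. at peak flow, extended to the zero-volume axis);
#' * `fef25` -- flow at the instant 25% of FVC has been exhaled
#'   (linearly interpolated at the crossing);
#' * `fif25` -- inspiratory flow magnitude at the instant 25% of FVC has
#'   been inhaled during the maximal inspiration.
#'
#' The forced expiration runs from the segment's expiratory onset until
#' the flow first returns below zero (or the segment ends). `fev1` is `NA`
#' (with a warning) when less than one second of expiration is available.
#'
#' @param flow A [flow_trace()].
#' @param segment An FVC segment row (see [segment_breaths()]).
#' @return An `fvc_vitals` list: `fvc`, `fev1`, `pef`, `fef25`, `fif25`.
#' @export
compute_fvc_vitals <- function(flow, segment) {
  segment <- as.list(segment)
  w <- trace_window(flow, segment$start_time, segment$end_time)
  if (length(w$times) < 3L) stop("segment too short", call. = FALSE)
  onset <- if (!is.null(segment$expiratory_onset) && is.finite(segment$expiratory_onset)) {
    segment$expiratory_onset
  } else {
    segment$start_time
  }

  exp_sel <- w$times >= onset
  te <- w$times[exp_sel]
  fe <- w$values[exp_sel]
  if (length(te) < 3L) stop("no expiratory limb after the onset", call. = FALSE)
  # expiration ends when flow first returns negative after the peak
  i_peak <- which.max(fe)
  i_end <- length(te)
  after <- which(fe[(i_peak + 1L):length(fe)] < 0)
  if (length(after)) i_end <- i_peak + after[1L] - 1L
  te <- te[seq_len(i_end)]
  fe <- fe[seq_len(i_end)]

  vol <- cumtrapz_vec(te, fe)
  fvc <- vol[length(vol)]
  pef <- max(fe)
  t_peak <- te[which.max(fe)]

  # back-extrapolated time zero: tangent of the volume curve at its
  # steepest slope (slope = PEF at t_peak) intersected with volume = 0
  v_peak <- approx(te, vol, xout = t_peak, rule = 2)$y
  t0 <- t_peak - v_peak / pef
  v_at <- function(tt) {
    tt <- pmin(pmax(tt, te[1L]), te[length(te)])
    approx(te, vol, xout = tt, rule = 2)$y
  }
  if (te[length(te)] - t0 < 1) {
    warning("maneuver has less than 1 s of expiration after time zero; FEV1 undefined")
    fev1 <- NA_real_
  } else {
    v0 <- if (t0 < te[1L]) 0 else v_at(t0)
    fev1 <- v_at(t0 + 1) - v0
  }

  fef25 <- interp_at_crossing(vol, fe, 0.25 * fvc)

  # inspiratory limb: from segment start to the onset
  ins_sel <- w$times <= onset
  fif25 <- NA_real_
  if (sum(ins_sel) >= 3L) {
    ti <- w$times[ins_sel]
    fi <- w$values[ins_sel]
    inhaled <- cumtrapz_vec(ti, -fi)
    fif25 <- abs(interp_at_crossing(inhaled, fi, 0.25 * fvc))
  }

  fvc_vitals(fvc, fev1, pef, fef25, fif25)
}

#' @export
print.fvc_vitals <- function(x, ...) {
  cat(sprintf("<fvc_vitals> FVC %.3f L | FEV1 %.3f L | PEF %.3f L/s | FEF25 %.3f L/s | FIF25 %.3f L/s\n",
              x$fvc, x$fev1, x$pef, x$fef25, x$fif25))
  invisible(x)
}

#' Mean tidal volume over the tidal segments of a session
#'
#' Tidal volume is reported as the mean per-cycle expired volume (integral
#' of the positive flow) over all tidal segments.
#'
#' @param flow A [flow_trace()].
#' @param segments Segment table from [segment_breaths()] or session truth
#'   labels.
#' @return Mean tidal volume in L (NA when no tidal segments exist).
#' @export
mean_tidal_volume <- function(flow, segments) {
  tid <- segments[segments$kind == "tidal", , drop = FALSE]
  if (!nrow(tid)) return(NA_real_)
  vols <- vapply(seq_len(nrow(tid)), function(k) {
    w <- trace_window(flow, tid$start_time[k], tid$end_time[k])
    if (length(w$times) < 2L) return(NA_real_)
    pracma::trapz(w$times, pmax(w$values, 0))
  }, 0)
  mean(vols, na.rm = TRUE)
}
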