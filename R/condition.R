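# Preprocessing chain: differential pressure, tail-offset removal,
# zero-phase smoothing, rate alignment onto a common 10 ms grid.

#' Differential pressure between the inside and outside sensors
#'
#' Sample-wise inside minus outside pressure after linearly interpolating
#' the outside trace onto the inside trace's timestamps, restricted to the
#' overlapping time span. The result removes the common atmospheric
#' baseline; what remains is the mask overpressure plus the inter-sensor
#' manufacturing offset (removed later from the zero-flow tail).
#'
#' @param inside,outside [pressure_trace()]s with overlapping spans.
#' @return A [pressure_trace()] of the differential, labelled after the pair.
#' @export
differential_pressure <- function(inside, outside) {
  stopifnot(inherits(inside, "pressure_trace"), inherits(outside, "pressure_trace"))
  t0 <- max(trace_start(inside), trace_start(outside))
  t1 <- min(trace_end(inside), trace_end(outside))
  if (t1 <= t0) stop("inside and outside traces do not overlap in time", call. = FALSE)
  keep <- inside$times >= t0 & inside$times <= t1
  times <- inside$times[keep]
  dp <- inside$values[keep] - trace_interp(outside, times)
  pressure_trace(times, dp, sample_rate = inside$sample_rate,
                 label = paste0(inside$label, "-", outside$label))
}

#' Offset from the zero-flow tail of a recording
#'
#' The arithmetic mean of all samples in the final `tail_duration` seconds
#' of the trace. The recording protocol ends with the mask taken off, so
#' this window sees zero true flow and its mean estimates the constant
#' instrument offset.
#'
#' @param trace A [pressure_trace()] or [flow_trace()].
#' @param tail_duration Tail window length in seconds (default 0.5).
#' @return The offset, in the trace's unit.
#' @export
estimate_tail_offset <- function(trace, tail_duration = 0.5) {
  stopifnot(inherits(trace, "spiro_trace"), tail_duration > 0)
  if (trace_duration(trace) <= tail_duration) {
    stop(sprintf("trace duration (%.3f s) must exceed `tail_duration` (%.3f s)",
                 trace_duration(trace), tail_duration), call. = FALSE)
  }
  sel <- trace$times > trace_end(trace) - tail_duration
  mean(trace$values[sel])
}

# one causal boxcar pass with reflect padding; length preserved
boxcar_forward <- function(x, k) {
  if (k == 1L) return(x)
  n <- length(x)
  pad <- c(x[k:1], x, x[n:(n - k + 1)])
  sm <- as.numeric(stats::filter(pad, rep(1 / k, k), sides = 1))
  sm[(k + k):(k + k + n - 1L)]
}

#' Zero-phase moving-average smoothing
#'
#' A boxcar of width `kernel` samples applied forward and then backward
#' over the trace. The cascade has an exactly symmetric impulse response,
#' so the net phase response is zero: peaks are smoothed but not shifted
#' in time. Edges are handled by reflect-padding with `kernel` samples,
#' which keeps the DC gain at one so constant signals (in particular the
#' zero-flow tail used for offset estimation) pass unchanged.
#'
#' @param trace A [pressure_trace()] or [flow_trace()].
#' @param kernel Boxcar width in samples (>= 1; default 10).
#' @return A trace of the same class and length.
#' @export
zero_phase_smooth <- function(trace, kernel = 10) {
  stopifnot(inherits(trace, "spiro_trace"), kernel >= 1)
  kernel <- as.integer(kernel)
  if (length(trace$times) <= 3L * kernel) {
    stop("trace too short for zero-phase smoothing (need length > 3 * kernel)",
         call. = FALSE)
  }
  v <- boxcar_forward(trace$values, kernel)
  v <- rev(boxcar_forward(rev(v), kernel))
  new_trace(trace$times, v, trace$unit, trace$sample_rate, trace$label)
}

#' Downsample by two-sample averaging
#'
#' Halves the sampling rate by averaging consecutive sample pairs:
#' `output[k] = (input[2k-1] + input[2k]) / 2` with the timestamp at the
#' pair's midpoint -- the scheme used to bring 100 Hz barometer streams to
#' the 50 Hz reference-spirometer rate. A trailing odd sample is dropped
#' with a warning.
#'
#' @param trace A uniformly sampled trace.
#' @return A trace at half the input rate.
#' @export
downsample_two_average <- function(trace) {
  stopifnot(inherits(trace, "spiro_trace"))
  n <- length(trace$times)
  if (n %% 2L == 1L) {
    warning("odd sample count: dropping the trailing sample before pairing")
    n <- n - 1L
  }
  i1 <- seq(1L, n, by = 2L)
  i2 <- i1 + 1L
  new_trace((trace$times[i1] + trace$times[i2]) / 2,
            (trace$values[i1] + trace$values[i2]) / 2,
            trace$unit,
            sample_rate = if (is.null(trace$sample_rate)) NULL else trace$sample_rate / 2,
            label = trace$label)
}

#' Condition a sensor pair and reference flow for calibration
#'
#' The full preprocessing chain producing the `(x, y)` samples the
#' calibration models are fitted on: differential pressure (inside minus
#' outside), tail-offset subtraction, zero-phase smoothing, optional
#' two-sample downsampling to the reference rate, and linear interpolation
#' of both channels onto a common uniform grid (default 10 ms spacing).
#' The reference flow receives its own tail-offset subtraction only.
#'
#' @param inside,outside [pressure_trace()]s.
#' @param reference_flow A [flow_trace()].
#' @param tail_s Zero-flow tail window used for offset estimation, s.
#' @param kernel Zero-phase boxcar width in samples (1 disables smoothing).
#' @param grid_ms Pairing grid spacing in milliseconds.
#' @param downsample If `TRUE` (default) and the pressure stream samples at
#'   twice `target_rate`, apply [downsample_two_average()] before pairing,
#'   mirroring the hardware path.
#' @param target_rate Rate the pressure stream is downsampled towards, Hz.
#' @return A `conditioned_pair`: list with `grid_times` (s), `dp` (Pa,
#'   offset-corrected smoothed differential pressure), `flow` (L/s,
#'   offset-corrected reference), and the estimated `dp_offset` /
#'   `flow_offset`.
#' @export
make_conditioned_pair <- function(inside, outside, reference_flow,
                                  tail_s = 0.5, kernel = 10, grid_ms = 10,
                                  downsample = TRUE, target_rate = 50) {
  dp <- differential_pressure(inside, outside)
  dp_offset <- estimate_tail_offset(dp, tail_s)
  dp$values <- dp$values - dp_offset
  dp <- zero_phase_smooth(dp, kernel)
  if (downsample && !is.null(dp$sample_rate) &&
      isTRUE(all.equal(dp$sample_rate, 2 * target_rate))) {
    dp <- downsample_two_average(dp)
  }
  flow_offset <- estimate_tail_offset(reference_flow, tail_s)
  flow <- reference_flow
  flow$values <- flow$values - flow_offset

  step <- grid_ms / 1000
  t0 <- max(trace_start(dp), trace_start(flow))
  t1 <- min(trace_end(dp), trace_end(flow))
  if (t1 <= t0) stop("pressure and flow traces do not overlap in time", call. = FALSE)
  grid <- seq(t0, t1, by = step)
  structure(
    list(grid_times = grid,
         dp = trace_interp(dp, grid),
         flow = trace_interp(flow, grid),
         grid_ms = grid_ms,
         dp_offset = dp_offset, flow_offset = flow_offset),
    class = "conditioned_pair"
  )
}

#' @export
print.conditioned_pair <- function(x, ...) {
  cat(sprintf("<conditioned_pair> %d samples on a %g ms grid (%.2f..%.2f s)\n",
              length(x$grid_times), x$grid_ms,
              min(x$grid_times), max(x$grid_times)))
  cat(sprintf("  dp offset: %.4g Pa | flow offset: %.4g L/s\n",
              x$dp_offset, x$flow_offset))
  invisible(x)
}

# normalise fit inputs: accept a conditioned_pair, a list of them (pooled),
# or a data.frame/list with dp & flow
as_xy <- function(pairs) {
  if (inherits(pairs, "conditioned_pair")) {
    return(list(x = pairs$dp, y = pairs$flow))
  }
  if (is.list(pairs) && length(pairs) && all(vapply(pairs, inherits, TRUE, "conditioned_pair"))) {
    return(list(x = unlist(lapply(pairs, `[[`, "dp")),
                y = unlist(lapply(pairs, `[[`, "flow"))))
  }
  if (!is.null(pairs$dp) && !is.null(pairs$flow)) {
    return(list(x = as.numeric(pairs$dp), y = as.numeric(pairs$flow)))
  }
  stop("`pairs` must be a conditioned_pair, a list of them, or have $dp and $flow",
       call. = FALSE)
}
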