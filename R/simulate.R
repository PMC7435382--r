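# Synthetic breathing sessions: paired (inside/outside barometer, reference
# spirometer) recordings with the statistical structure the calibration
# chain assumes, so every downstream stage is testable without hardware.

#' Subject breathing profile
#'
#' Parameters of one synthetic subject: tidal breathing (volume and rate),
#' forced-maneuver shape (total capacity, peak flows, expiratory decay time
#' constant) and the subject's ground-truth pressure-flow law. The
#' ground-truth law is a root-family curve
#' `flow = c_pos * sqrt(dp)` for `dp > 0` and `flow = c_neg * sqrt(-dp)`
#' for `dp < 0` (flow in L/s, `dp` in Pa), i.e. the square-root relation
#' the calibration stage assumes, with per-subject coefficients standing in
#' for the friction and flow-unevenness a real mask introduces.
#'
#' @param tidal_volume Tidal volume in L; must be below `fvc_total`.
#' @param respiratory_rate Breaths per minute.
#' @param fvc_total Volume of the maximal inspiration in L.
#' @param peak_expiratory_flow Peak forced expiratory flow in L/s (1-12).
#' @param peak_inspiratory_flow Peak forced inspiratory flow in L/s.
#' @param expiratory_decay_tau Time constant of the forced-expiration decay, s.
#' @param pressure_gain List with elements `pos` (> 0) and `neg` (< 0):
#'   coefficients of the subject's square-root pressure-flow law, in
#'   L s^-1 Pa^-1/2.
#' @param seed Integer seed associated with this subject.
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(tidal_volume = 0.5,
                            respiratory_rate = 14,
                            fvc_total = 4,
                            peak_expiratory_flow = 8,
                            peak_inspiratory_flow = 4,
                            expiratory_decay_tau = 0.5,
                            pressure_gain = list(pos = 0.1744, neg = -0.1373),
                            seed = 1L) {
  vols <- c(tidal_volume = tidal_volume, respiratory_rate = respiratory_rate,
            fvc_total = fvc_total, peak_expiratory_flow = peak_expiratory_flow,
            peak_inspiratory_flow = peak_inspiratory_flow,
            expiratory_decay_tau = expiratory_decay_tau)
  assert_finite(vols, "profile parameters")
  if (any(vols <= 0)) stop("all profile volumes/flows/rates must be positive", call. = FALSE)
  if (tidal_volume >= fvc_total) {
    stop("`tidal_volume` must be smaller than `fvc_total`", call. = FALSE)
  }
  if (peak_expiratory_flow < 1 || peak_expiratory_flow > 12) {
    stop("`peak_expiratory_flow` must lie within 1-12 L/s", call. = FALSE)
  }
  if (!is.list(pressure_gain) || is.null(pressure_gain$pos) || is.null(pressure_gain$neg) ||
      pressure_gain$pos <= 0 || pressure_gain$neg >= 0) {
    stop("`pressure_gain` must be list(pos > 0, neg < 0)", call. = FALSE)
  }
  structure(
    list(tidal_volume = tidal_volume, respiratory_rate = respiratory_rate,
         fvc_total = fvc_total, peak_expiratory_flow = peak_expiratory_flow,
         peak_inspiratory_flow = peak_inspiratory_flow,
         expiratory_decay_tau = expiratory_decay_tau,
         pressure_gain = pressure_gain, seed = as.integer(seed)),
    class = "subject_profile"
  )
}

#' Barometric sensor specification
#'
#' Noise and quantisation model of one barometer grade. Two datasheet-grade
#' presets exist, both sampling at 100 Hz: grade "A" (noise SD 0.2 Pa,
#' output resolution 0.18 Pa) and grade "B" (noise SD 0.03 Pa, resolution
#' 0.016 Pa). Each physical sensor additionally carries a constant
#' per-sensor pressure offset drawn uniformly from `+/- offset_range`.
#'
#' @param grade `"A"` or `"B"` preset; ignored when all numeric fields are
#'   supplied explicitly.
#' @param noise_sd Gaussian read noise SD in Pa.
#' @param resolution Quantisation step in Pa (0 disables quantisation).
#' @param offset_range Half-width of the uniform per-sensor offset, Pa.
#' @param sample_rate Sampling rate in Hz.
#' @return A `sensor_spec` object.
#' @export
sensor_spec <- function(grade = c("A", "B"), noise_sd = NULL, resolution = NULL,
                        offset_range = 50, sample_rate = 100) {
  grade <- match.arg(grade)
  preset <- switch(grade,
                   A = list(noise_sd = 0.2, resolution = 0.18),
                   B = list(noise_sd = 0.03, resolution = 0.016))
  if (is.null(noise_sd)) noise_sd <- preset$noise_sd
  if (is.null(resolution)) resolution <- preset$resolution
  stopifnot(noise_sd >= 0, resolution >= 0, offset_range >= 0, sample_rate > 0)
  structure(
    list(grade = grade, noise_sd = noise_sd, resolution = resolution,
         offset_range = offset_range, sample_rate = sample_rate),
    class = "sensor_spec"
  )
}

# ---- ground-truth pressure-flow law ---------------------------------------

# flow (L/s) from differential pressure (Pa) under a subject's root law
root_law_flow <- function(dp, gain) {
  ifelse(dp >= 0, gain$pos * sqrt(pmax(dp, 0)), gain$neg * sqrt(pmax(-dp, 0)))
}

# inverse: differential pressure (Pa) from flow (L/s); requires a monotone
# law (pos > 0, neg < 0), which subject_profile() guarantees
root_law_pressure <- function(flow, gain) {
  if (gain$pos <= 0 || gain$neg >= 0) {
    stop("ground-truth pressure-flow law is not monotone (need pos > 0, neg < 0)",
         call. = FALSE)
  }
  ifelse(flow >= 0, (flow / gain$pos)^2, -(flow / gain$neg)^2)
}

# ---- analytic breathing programs ------------------------------------------
# A "program" is a list of segments, each with a duration and a vectorised
# flow function of local time; sampling happens once, on a uniform grid.

tidal_cycle_segment <- function(profile) {
  T_cycle <- 60 / profile$respiratory_rate
  amp <- pi * profile$tidal_volume / T_cycle
  th <- T_cycle / 2
  list(kind = "tidal", duration = T_cycle,
       fn = function(t) {
         ifelse(t < th, -amp * sin(pi * t / th), amp * sin(pi * (t - th) / th))
       })
}

fvc_maneuver_segment <- function(profile, exp_duration = 6,
                                 rise = c("instant", "smooth"), rise_time = 0.12,
                                 plateau_time = 0.15) {
  rise <- match.arg(rise)
  if (profile$expiratory_decay_tau <= 0) stop("tau must be positive", call. = FALSE)
  pef <- profile$peak_expiratory_flow
  pif <- profile$peak_inspiratory_flow
  tau <- profile$expiratory_decay_tau
  ti <- pi * profile$fvc_total / (2 * pif)  # half-sine inspiration of volume fvc_total
  fn <- if (rise == "instant") {
    function(t) {
      ifelse(t < ti, -pif * sin(pi * t / ti), pef * exp(-(t - ti) / tau))
    }
  } else {
    # realistic rounded peak: half-sine rise, a brief near-peak plateau,
    # then the exponential decline
    r <- rise_time
    p <- plateau_time
    function(t) {
      te <- t - ti
      ifelse(t < ti, -pif * sin(pi * t / ti),
             ifelse(te < r, pef * sin(pi * te / (2 * r)),
                    ifelse(te < r + p, pef, pef * exp(-(te - r - p) / tau))))
    }
  }
  list(kind = "fvc", duration = ti + exp_duration, fn = fn,
       expiratory_onset = ti, rise = rise, rise_time = rise_time,
       plateau_time = plateau_time, exp_duration = exp_duration)
}

zero_segment <- function(duration) {
  list(kind = "zero", duration = duration, fn = function(t) rep(0, length(t)))
}

sample_program <- function(segments, sample_rate) {
  dur <- vapply(segments, `[[`, 0, "duration")
  starts <- cumsum(c(0, dur))
  total <- starts[length(starts)]
  dt <- 1 / sample_rate
  times <- seq(0, total - dt / 2, by = dt)
  idx <- findInterval(times, starts, rightmost.closed = FALSE)
  idx[idx > length(segments)] <- length(segments)
  values <- numeric(length(times))
  for (k in seq_along(segments)) {
    sel <- idx == k
    if (any(sel)) values[sel] <- segments[[k]]$fn(times[sel] - starts[k])
  }
  labels <- data.frame(
    kind = vapply(segments, `[[`, "", "kind"),
    start_time = starts[-length(starts)],
    end_time = starts[-1L],
    expiratory_onset = vapply(segments, function(s) {
      if (is.null(s$expiratory_onset)) NA_real_ else s$expiratory_onset
    }, 0) + starts[-length(starts)]
  )
  list(trace = flow_trace(times, values, sample_rate = sample_rate, label = "truth"),
       labels = labels)
}

# ---- public simulators -----------------------------------------------------

#' Simulate tidal breathing flow
#'
#' Smooth periodic flow built from sinusoidal half-waves: each cycle is one
#' inspiratory half-sine followed by one expiratory half-sine, both scaled
#' so the inhaled and exhaled volume per cycle equal the profile's tidal
#' volume (zero net volume per cycle). Peak flow of each half-wave is
#' `pi * TV / T` for cycle period `T = 60 / rate`.
#'
#' @param profile A [subject_profile()].
#' @param n_cycles Number of breathing cycles (>= 1).
#' @param sample_rate Sampling rate in Hz.
#' @return A [flow_trace()].
#' @export
simulate_tidal_flow <- function(profile, n_cycles, sample_rate = 100) {
  stopifnot(inherits(profile, "subject_profile"), n_cycles >= 1)
  segs <- replicate(n_cycles, tidal_cycle_segment(profile), simplify = FALSE)
  sample_program(segs, sample_rate)$trace
}

#' Simulate one forced-vital-capacity maneuver
#'
#' The maneuver is a maximal-inspiration half-sine of volume `fvc_total`
#' (peak `peak_inspiratory_flow`) followed by a forced expiration. With
#' `rise = "instant"` the expiration is the analytic template
#' `F(t) = PEF * exp(-t / tau)` whose vitals have closed forms:
#' `FVC = PEF*tau*(1 - exp(-T/tau))`, `FEV1 = PEF*tau*(1 - exp(-1/tau))`,
#' `FEF25 = PEF - 0.25*FVC/tau`, and `FIF25` from the inspiratory
#' half-sine. With `rise = "smooth"` the peak is rounded as real maneuvers
#' are -- a half-sine onset of duration `rise_time`, a near-peak plateau of
#' `plateau_time`, then the decay -- and the returned vitals are computed
#' numerically from the template sampled at 1 kHz.
#'
#' @inheritParams simulate_tidal_flow
#' @param exp_duration Forced-expiration duration in s.
#' @param rise `"instant"` (closed-form vitals) or `"smooth"`.
#' @param rise_time Half-sine onset duration for `rise = "smooth"`, s.
#' @param plateau_time Near-peak plateau duration for `rise = "smooth"`, s.
#' @return A list with elements `flow` (a [flow_trace()]) and `vitals`
#'   (an `fvc_vitals` list: fvc, fev1, pef, fef25, fif25, all template
#'   ground truth).
#' @export
simulate_fvc_flow <- function(profile, sample_rate = 100, exp_duration = 6,
                              rise = c("instant", "smooth"), rise_time = 0.12,
                              plateau_time = 0.15) {
  stopifnot(inherits(profile, "subject_profile"))
  rise <- match.arg(rise)
  seg <- fvc_maneuver_segment(profile, exp_duration, rise, rise_time, plateau_time)
  sampled <- sample_program(list(seg), sample_rate)
  vitals <- fvc_template_vitals(profile, exp_duration, rise, rise_time, plateau_time)
  list(flow = sampled$trace, vitals = vitals, labels = sampled$labels)
}

fvc_vitals <- function(fvc, fev1, pef, fef25, fif25) {
  structure(list(fvc = fvc, fev1 = fev1, pef = pef, fef25 = fef25, fif25 = fif25),
            class = "fvc_vitals")
}

# Closed-form (instant rise) or 1 kHz numeric (smooth rise) template vitals.
fvc_template_vitals <- function(profile, exp_duration, rise, rise_time,
                                plateau_time = 0.15) {
  pef <- profile$peak_expiratory_flow
  tau <- profile$expiratory_decay_tau
  if (rise == "instant") {
    fvc <- pef * tau * (1 - exp(-exp_duration / tau))
    fev1 <- pef * tau * (1 - exp(-min(1, exp_duration) / tau))
    fef25 <- pef - 0.25 * fvc / tau
    # inspiratory half-sine of volume fvc_total: flow magnitude when 25% of
    # FVC has been inhaled
    frac <- pmin(1, 0.25 * fvc / profile$fvc_total)
    fif25 <- profile$peak_inspiratory_flow * sqrt(1 - (1 - 2 * frac)^2)
    fvc_vitals(fvc, fev1, pef, fef25, fif25)
  } else {
    seg <- fvc_maneuver_segment(profile, exp_duration, "smooth", rise_time, plateau_time)
    sampled <- sample_program(list(seg), 1000)
    compute_fvc_vitals(sampled$trace, as.list(sampled$labels[1, ]))
  }
}

#' Corrupt a ground-truth flow into a differential barometer pair
#'
#' Inverts the subject's ground-truth square-root pressure-flow law to get
#' the true inside-mask overpressure, then applies the sensor model: inside
#' pressure = atmospheric + true differential + per-sensor offset +
#' Gaussian read noise + quantisation; outside = atmospheric + its own
#' offset + noise + quantisation. Both traces are sampled on the sensor's
#' rate grid. Deterministic for a given seed.
#'
#' @param truth_flow Ground-truth [flow_trace()] (uniformly sampled).
#' @param profile A [subject_profile()] (supplies the pressure-flow law).
#' @param spec A [sensor_spec()].
#' @param seed Integer seed for offsets and noise.
#' @param atmospheric_pressure Baseline pressure in Pa.
#' @return List with `inside` and `outside` [pressure_trace()]s.
#' @export
flow_to_sensor_traces <- function(truth_flow, profile, spec = sensor_spec("A"),
                                  seed = 1L, atmospheric_pressure = 101325) {
  stopifnot(inherits(truth_flow, "flow_trace"), inherits(profile, "subject_profile"),
            inherits(spec, "sensor_spec"))
  with_seed(seed, {
    rate <- spec$sample_rate
    if (!is.null(truth_flow$sample_rate) &&
        isTRUE(all.equal(truth_flow$sample_rate, rate))) {
      times <- truth_flow$times
      flow <- truth_flow$values
    } else {
      times <- seq(trace_start(truth_flow), trace_end(truth_flow), by = 1 / rate)
      flow <- trace_interp(truth_flow, times)
    }
    dp_true <- root_law_pressure(flow, profile$pressure_gain)
    offsets <- runif(2, -spec$offset_range, spec$offset_range)
    n <- length(times)
    corrupt <- function(base, offset) {
      v <- base + offset + rnorm(n, 0, spec$noise_sd)
      if (spec$resolution > 0) v <- round(v / spec$resolution) * spec$resolution
      v
    }
    inside <- corrupt(atmospheric_pressure + dp_true, offsets[1])
    outside <- corrupt(rep(atmospheric_pressure, n), offsets[2])
    list(
      inside = pressure_trace(times, inside, sample_rate = rate, label = "inside"),
      outside = pressure_trace(times, outside, sample_rate = rate, label = "outside")
    )
  })
}

#' Simulate complete recording sessions for a cohort
#'
#' For each subject: `tidal_between` tidal cycles, then `n_fvc` forced
#' maneuvers each followed by `tidal_between` tidal cycles, then a
#' zero-flow tail (mask off) used downstream for offset estimation. Each
#' maneuver's effort is jittered downward (uniform scale on
#' `[1 - 2 * effort_jitter, 1]` for PEF and inspired volume, symmetric for
#' tau) so repeated maneuvers vary as real repeated efforts do while never
#' exceeding the profile's stated peak flow. The reference spirometer
#' channel is the truth flow
#' resampled to `reference_rate` plus Gaussian instrument noise and a
#' constant offset (both configurable, may be zero).
#'
#' @param profiles List of [subject_profile()]s (>= 1).
#' @param spec A [sensor_spec()].
#' @param seed Master seed; all per-subject randomness derives from it.
#' @param n_fvc Forced maneuvers per session.
#' @param tidal_between Tidal cycles before and between maneuvers (>= 1).
#' @param exp_duration Forced-expiration duration, s.
#' @param rise Forced-expiration onset shape (see [simulate_fvc_flow()]).
#' @param rise_time Onset duration for `rise = "smooth"`, s.
#' @param plateau_time Near-peak plateau duration for `rise = "smooth"`, s.
#' @param tail_s Zero-flow tail duration, s (>= 0.5).
#' @param effort_jitter Relative per-maneuver effort variability.
#' @param reference_rate Reference spirometer rate, Hz.
#' @param reference_noise_sd Reference instrument noise SD, L/s.
#' @param reference_offset Constant reference offset, L/s.
#' @param atmospheric_pressure Baseline pressure, Pa.
#' @return A list of `spiro_session` objects, each with elements `inside`,
#'   `outside`, `reference_flow`, `truth_flow`, `truth_vitals`,
#'   `segment_labels`, `profile`.
#' @export
simulate_session <- function(profiles, spec = sensor_spec("A"), seed = 1L,
                             n_fvc = 10, tidal_between = 5,
                             exp_duration = 6, rise = c("smooth", "instant"),
                             rise_time = 0.12, plateau_time = 0.15, tail_s = 1,
                             effort_jitter = 0.1,
                             reference_rate = 50, reference_noise_sd = 0.02,
                             reference_offset = 0.01,
                             atmospheric_pressure = 101325) {
  if (inherits(profiles, "subject_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1, tail_s >= 0.5, tidal_between >= 1)
  rise <- match.arg(rise)
  lapply(seq_along(profiles), function(i) {
    profile <- profiles[[i]]
    sseed <- child_seed(seed, i)
    with_seed(sseed, {
      segs <- replicate(tidal_between, tidal_cycle_segment(profile), simplify = FALSE)
      truth_vitals <- vector("list", n_fvc)
      for (m in seq_len(n_fvc)) {
        p <- profile
        p$peak_expiratory_flow <- p$peak_expiratory_flow * runif(1, 1 - 2 * effort_jitter, 1)
        p$expiratory_decay_tau <- p$expiratory_decay_tau * runif(1, 1 - effort_jitter, 1 + effort_jitter)
        p$fvc_total <- p$fvc_total * runif(1, 1 - effort_jitter, 1)
        segs <- c(segs, list(fvc_maneuver_segment(p, exp_duration, rise, rise_time, plateau_time)))
        truth_vitals[[m]] <- fvc_template_vitals(p, exp_duration, rise, rise_time, plateau_time)
        segs <- c(segs, replicate(tidal_between, tidal_cycle_segment(profile),
                                  simplify = FALSE))
      }
      segs <- c(segs, list(zero_segment(tail_s)))
      sampled <- sample_program(segs, spec$sample_rate)
      truth_flow <- sampled$trace

      sensors <- flow_to_sensor_traces(truth_flow, profile, spec,
                                       seed = child_seed(sseed, 1),
                                       atmospheric_pressure = atmospheric_pressure)
      ref_times <- seq(trace_start(truth_flow), trace_end(truth_flow),
                       by = 1 / reference_rate)
      ref_vals <- trace_interp(truth_flow, ref_times) + reference_offset +
        rnorm(length(ref_times), 0, reference_noise_sd)
      structure(
        list(inside = sensors$inside, outside = sensors$outside,
             reference_flow = flow_trace(ref_times, ref_vals,
                                         sample_rate = reference_rate,
                                         label = "reference"),
             truth_flow = truth_flow,
             truth_vitals = truth_vitals,
             segment_labels = sampled$labels,
             profile = profile),
        class = "spiro_session"
      )
    })
  })
}

#' @export
print.spiro_session <- function(x, ...) {
  n_fvc <- sum(x$segment_labels$kind == "fvc")
  cat(sprintf("<spiro_session> %.1f s, %d FVC maneuvers, sensors at %g Hz, reference at %g Hz\n",
              trace_duration(x$truth_flow), n_fvc,
              x$inside$sample_rate, x$reference_flow$sample_rate))
  invisible(x)
}

#' Draw a random cohort of subject profiles
#'
#' Subject parameters are drawn from ranges typical of healthy adults:
#' tidal volume 0.4-0.7 L, respiratory rate 10-18 /min, peak expiratory
#' flow 6-11 L/s, expiratory decay 0.35-0.6 s, with the inspired capacity
#' matched to the expiratory template. The square-root pressure-gain
#' coefficients are mostly a property of the shared mask/orifice geometry,
#' so they vary only moderately (+/- 10%) around the 0.17 / -0.14
#' L s^-1 Pa^-1/2 scale, reflecting fit and seal differences between
#' wearers.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return List of [subject_profile()]s.
#' @export
random_profiles <- function(n, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pef <- runif(1, 6, 11)
      tau <- runif(1, 0.3, 0.5)
      # inspired capacity matched to the smooth-template expired volume
      # (rise 0.12 s + plateau 0.15 s + exponential tail)
      subject_profile(
        tidal_volume = runif(1, 0.4, 0.7),
        respiratory_rate = runif(1, 10, 18),
        fvc_total = pef * (2 * 0.12 / pi + 0.15 + tau) * 0.98,
        peak_expiratory_flow = pef,
        peak_inspiratory_flow = runif(1, 0.4, 0.6) * pef,
        expiratory_decay_tau = tau,
        pressure_gain = list(pos = 0.1744 * runif(1, 0.9, 1.1),
                             neg = -0.1373 * runif(1, 0.9, 1.1)),
        seed = child_seed(seed, i)
      )
    })
  })
}
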