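# Shared fixture builders; everything is generated in code under fixed seeds.

# A cohort of sessions with the given noise setup; warnings from the
# odd-sample downsampling drop are irrelevant to what tests assert.
quiet_sessions <- function(n_subjects, seed, spec = sensor_spec("A"), ...) {
  suppressWarnings(
    simulate_session(random_profiles(n_subjects, seed = seed), spec, seed = seed, ...)
  )
}

# A noise-free single-subject session whose conditioned pairs lie exactly
# on the generating square-root law: identity smoothing, no resampling
# (sensor and reference both at 100 Hz, matching the 10 ms pairing grid).
noise_free_session <- function(seed = 3, gain = list(pos = 0.1744, neg = -0.1373),
                               n_fvc = 2, tidal_between = 2) {
  prof <- subject_profile(pressure_gain = gain)
  suppressWarnings(simulate_session(
    prof,
    sensor_spec("A", noise_sd = 0, resolution = 0, offset_range = 0),
    seed = seed, n_fvc = n_fvc, tidal_between = tidal_between,
    reference_rate = 100, reference_noise_sd = 0, reference_offset = 0
  ))[[1]]
}

exact_condition_args <- list(kernel = 1, downsample = FALSE)

# Instant-rise template profile whose expiratory onset (the inspiration
# duration pi * fvc_total / (2 * PIF) = 1.6 s) falls exactly on both the
# 1 ms and 10 ms sampling grids, so grid-accuracy tests measure estimator
# discretisation rather than the phase of the sampled peak.
aligned_fvc_profile <- function() {
  subject_profile(fvc_total = 12.8 / pi, peak_expiratory_flow = 8,
                  peak_inspiratory_flow = 4, expiratory_decay_tau = 0.5)
}

# root-family design matrix for the explicit normal-equations oracle
oracle_root_basis <- function(u, active) {
  cols <- list(a = u, b = rep(1, length(u)), c = sqrt(u),
               d = u^(1 / 3), e = u^(1 / 4))
  do.call(cbind, cols[active])
}

# independent least-squares oracle: explicit normal equations
oracle_lls <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))
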