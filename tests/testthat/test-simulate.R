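test_that("tidal cycles conserve volume and hit the half-sine peak", {
  prof <- subject_profile(tidal_volume = 0.5, respiratory_rate = 12)
  tr <- simulate_tidal_flow(prof, n_cycles = 1, sample_rate = 1000)
  t_cycle <- max(tr$times) + 1 / 1000
  expect_equal(t_cycle, 5, tolerance = 1e-3)            # 60 / rate
  # expiratory half integrates to TV, full cycle to 0
  expir <- tr$values > 0
  vol_exp <- pracma::trapz(tr$times[expir], tr$values[expir])
  expect_equal(vol_exp, 0.5, tolerance = 1e-3)
  vol_net <- pracma::trapz(tr$times, tr$values)
  expect_lt(abs(vol_net), 1e-6)
  # peak of a volume-TV half-sine over half the cycle: pi * TV / T
  expect_equal(max(tr$values), pi * 0.5 / 5, tolerance = 1e-4)
})

test_that("instant-rise forced maneuver matches its closed-form vitals", {
  prof <- subject_profile(fvc_total = 4, peak_expiratory_flow = 8,
                          peak_inspiratory_flow = 4, expiratory_decay_tau = 0.5)
  out <- simulate_fvc_flow(prof, sample_rate = 1000, exp_duration = 6)
  v <- out$vitals
  expect_equal(v$fvc, 8 * 0.5 * (1 - exp(-12)), tolerance = 1e-9)
  expect_equal(v$fvc, 4.000, tolerance = 1e-4)
  expect_equal(v$fev1, 4 * (1 - exp(-2)), tolerance = 1e-9)
  expect_equal(v$fev1, 3.459, tolerance = 1e-3)
  expect_equal(v$pef, 8)
  # flow after 1 L exhaled: V(t) = 4(1 - e^(-2t)) -> F = 8 * 0.75
  expect_equal(v$fef25, 6.0, tolerance = 1e-4)
  # 25% of FVC inhaled on a half-sine of volume fvc_total
  expect_equal(v$fif25, 4 * sin(pi / 3), tolerance = 1e-3)
})

test_that("sensor corruption inverts the root law and respects the noise model", {
  prof <- subject_profile(pressure_gain = list(pos = 0.1744, neg = -0.1373))
  # 1.744 L/s through the root2only law must sit at exactly +100 Pa
  expect_equal(barospiro:::root_law_pressure(1.744, prof$pressure_gain), 100)
  expect_equal(barospiro:::root_law_flow(100, prof$pressure_gain), 1.744)

  # zero flow, zero noise/offsets -> both sensors flat at Patmos
  flat <- flow_trace(seq(0, 2, by = 0.01), rep(0, 201), sample_rate = 100)
  clean <- sensor_spec("A", noise_sd = 0, resolution = 0, offset_range = 0)
  tr <- flow_to_sensor_traces(flat, prof, clean, seed = 5)
  expect_equal(tr$inside$values, rep(101325, 201))
  expect_equal(tr$outside$values, rep(101325, 201))

  # differential noise during a zero-flow span ~ sqrt(2) * noise_sd
  long_flat <- flow_trace(seq(0, 40, by = 0.01), rep(0, 4001), sample_rate = 100)
  noisy <- sensor_spec("A", noise_sd = 0.2, resolution = 0, offset_range = 10)
  tr2 <- flow_to_sensor_traces(long_flat, prof, noisy, seed = 5)
  dsd <- sd(tr2$inside$values - tr2$outside$values)
  expect_equal(dsd, sqrt(2) * 0.2, tolerance = 0.05)

  # quantisation keeps values on the resolution lattice
  quant <- sensor_spec("A", noise_sd = 0.2, resolution = 0.18, offset_range = 10)
  tr3 <- flow_to_sensor_traces(flat, prof, quant, seed = 5)
  lattice_dist <- abs(tr3$inside$values / 0.18 - round(tr3$inside$values / 0.18))
  expect_lt(max(lattice_dist), 1e-6)
})

test_that("sessions have the protocol structure and a zero-flow tail", {
  sess <- quiet_sessions(1, seed = 9, n_fvc = 10, tidal_between = 5)[[1]]
  labs <- sess$segment_labels
  expect_identical(sum(labs$kind == "fvc"), 10L)
  # >= 5 tidal cycles between consecutive maneuvers
  fvc_idx <- which(labs$kind == "fvc")
  gaps <- diff(fvc_idx) - 1
  expect_true(all(gaps >= 5))
  # tail: last segment is zero flow for >= 0.5 s
  tail_lab <- labs[nrow(labs), ]
  expect_identical(tail_lab$kind, "zero")
  expect_gte(tail_lab$end_time - tail_lab$start_time, 0.5)
  tail_vals <- sess$truth_flow$values[sess$truth_flow$times >= tail_lab$start_time]
  expect_true(all(tail_vals == 0))
  expect_length(sess$truth_vitals, 10L)
})

test_that("sessions are deterministic given the seed and distinct across subjects", {
  a <- quiet_sessions(2, seed = 21, n_fvc = 2, tidal_between = 2)
  b <- quiet_sessions(2, seed = 21, n_fvc = 2, tidal_between = 2)
  expect_identical(a[[1]]$inside$values, b[[1]]$inside$values)
  expect_identical(a[[2]]$reference_flow$values, b[[2]]$reference_flow$values)
  gains <- vapply(a, function(s) s$profile$pressure_gain$pos, 0)
  expect_gt(diff(range(gains)), 0)
})

test_that("maneuver flow never overshoots the profile peak expiratory flow", {
  sess <- quiet_sessions(3, seed = 13, n_fvc = 3, tidal_between = 2)
  for (s in sess) {
    expect_lte(max(s$truth_flow$values), s$profile$peak_expiratory_flow * 1.01)
  }
})

test_that("invalid profiles are rejected", {
  expect_error(subject_profile(tidal_volume = 5, fvc_total = 4), "smaller")
  expect_error(subject_profile(peak_expiratory_flow = 0.5), "1-12")
  expect_error(subject_profile(pressure_gain = list(pos = -1, neg = -1)), "pos > 0")
  expect_error(subject_profile(expiratory_decay_tau = -0.1), "positive")
})
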