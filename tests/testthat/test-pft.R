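test_that("segmentation finds labelled maneuvers and ignores sub-hysteresis noise", {
  sess <- quiet_sessions(1, seed = 23, n_fvc = 4, tidal_between = 3,
                         spec = sensor_spec("A", noise_sd = 0, resolution = 0,
                                            offset_range = 0))[[1]]
  segs <- segment_breaths(sess$truth_flow)
  expect_identical(sum(segs$kind == "fvc"), 4L)
  # onsets align with the truth labels to within one 10 ms sample
  truth_on <- sess$segment_labels$expiratory_onset[sess$segment_labels$kind == "fvc"]
  found_on <- segs$expiratory_onset[segs$kind == "fvc"]
  expect_equal(found_on, truth_on, tolerance = 0.011)

  # a pure tidal session yields no forced maneuvers
  tidal <- simulate_tidal_flow(subject_profile(), 6)
  segs_t <- segment_breaths(tidal)
  expect_identical(sum(segs_t$kind == "fvc"), 0L)

  # +/- 0.02 L/s noise sits below the hysteresis band: count unchanged
  withr::local_seed(1)
  noisy <- flow_trace(tidal$times,
                      tidal$values + runif(length(tidal$values), -0.02, 0.02))
  expect_identical(nrow(segment_breaths(noisy)), nrow(segs_t))

  # all-zero flow -> empty segmentation
  flat <- flow_trace(seq(0, 5, by = 0.01), rep(0, 501))
  expect_identical(nrow(segment_breaths(flat)), 0L)
})

test_that("cumulative volume integrates flow in liters", {
  t <- seq(0, 2, by = 0.001)
  const <- flow_trace(t, rep(1, length(t)))
  v <- cumulative_volume(const)
  expect_equal(v$values[length(v$values)], 2, tolerance = 1e-9)

  cyc <- simulate_tidal_flow(subject_profile(), 1, sample_rate = 1000)
  vc <- cumulative_volume(cyc)
  expect_lt(abs(vc$values[length(vc$values)]), 1e-6)

  prof <- subject_profile(fvc_total = 4, peak_expiratory_flow = 8,
                          peak_inspiratory_flow = 4, expiratory_decay_tau = 0.5)
  fv <- simulate_fvc_flow(prof, sample_rate = 1000)
  seg <- as.list(fv$labels[1, ])
  ve <- cumulative_volume(fv$flow, seg)
  expect_equal(max(ve$values), 4.000, tolerance = 5e-3)
})

test_that("sliding-window volume matches closed forms", {
  t <- seq(0, 4, by = 0.01)
  const <- flow_trace(t, rep(1, length(t)))
  sw <- sliding_window_volume(const, window = 0.5, step = 0.01)
  expect_equal(sw$values, rep(0.5, length(sw$values)), tolerance = 1e-12)

  flat <- flow_trace(t, rep(0, length(t)))
  expect_equal(max(abs(sliding_window_volume(flat)$values)), 0)

  # sin(2 pi t): windowed integral (1/2pi)(cos(2pi(t-.5)) - cos(2pi t)), max ~ 1/pi
  sine <- flow_trace(seq(0, 6, by = 0.001), sin(2 * pi * seq(0, 6, by = 0.001)))
  swv <- sliding_window_volume(sine, window = 0.5, step = 0.001)
  closed <- (cos(2 * pi * (swv$times - 0.5)) - cos(2 * pi * swv$times)) / (2 * pi)
  expect_equal(swv$values, closed, tolerance = 1e-5)
  expect_equal(max(swv$values), 1 / pi, tolerance = 1e-4)

  expect_error(sliding_window_volume(flow_trace(c(0, 0.1), c(0, 0)), 0.5), "window")
})

test_that("flow-volume loops start at zero volume at the expiratory onset", {
  prof <- aligned_fvc_profile()
  fv <- simulate_fvc_flow(prof, sample_rate = 1000)
  seg <- as.list(fv$labels[1, ])
  loop <- flow_volume_loop(fv$flow, seg)
  # instant-rise template: maximum flow is PEF, located at volume ~ 0
  expect_equal(max(loop$flow), 8, tolerance = 1e-6)
  expect_equal(loop$volume[which.max(loop$flow)], 0, tolerance = 0.01)

  expect_error(flow_volume_loop(fv$flow, modifyList(seg, list(kind = "tidal"))),
               "fvc")
  zs <- list(kind = "fvc", start_time = 0, end_time = 1, expiratory_onset = 0.5)
  flat <- flow_trace(seq(0, 1, by = 0.01), rep(0, 101))
  expect_error(flow_volume_loop(flat, zs), "degenerate")
})

test_that("vitals from the numeric pipeline match closed forms at both grids", {
  prof <- aligned_fvc_profile()
  truth <- simulate_fvc_flow(prof, sample_rate = 1000)$vitals

  for (setup in list(list(rate = 1000, tol = 0.001), list(rate = 100, tol = 0.01))) {
    fv <- simulate_fvc_flow(prof, sample_rate = setup$rate)
    v <- compute_fvc_vitals(fv$flow, as.list(fv$labels[1, ]))
    expect_equal(v$fvc, truth$fvc, tolerance = setup$tol)
    expect_equal(v$fev1, truth$fev1, tolerance = setup$tol)
    expect_equal(v$pef, truth$pef, tolerance = setup$tol)
    expect_equal(v$fef25, truth$fef25, tolerance = setup$tol)
    expect_equal(v$fif25, truth$fif25, tolerance = setup$tol)
    expect_lte(v$fev1, v$fvc)
    expect_gte(v$pef, v$fef25)
  }
})

test_that("vitals scale linearly with the flow signal", {
  prof <- subject_profile(fvc_total = 4, peak_expiratory_flow = 8,
                          peak_inspiratory_flow = 4, expiratory_decay_tau = 0.5)
  fv <- simulate_fvc_flow(prof, sample_rate = 1000)
  seg <- as.list(fv$labels[1, ])
  v1 <- compute_fvc_vitals(fv$flow, seg)
  doubled <- flow_trace(fv$flow$times, 2 * fv$flow$values)
  v2 <- compute_fvc_vitals(doubled, seg)
  for (nm in c("fvc", "fev1", "pef", "fef25", "fif25")) {
    expect_equal(v2[[nm]], 2 * v1[[nm]], tolerance = 1e-9)
  }
})

test_that("a flow plateau gives FEV1 = PEF x 1 s in the large-tau limit", {
  prof <- subject_profile(fvc_total = 25, peak_expiratory_flow = 5,
                          peak_inspiratory_flow = 6, expiratory_decay_tau = 1e6,
                          tidal_volume = 0.5)
  fv <- simulate_fvc_flow(prof, sample_rate = 1000, exp_duration = 4)
  v <- compute_fvc_vitals(fv$flow, as.list(fv$labels[1, ]))
  expect_equal(v$fev1, 5, tolerance = 1e-3)
})

test_that("short expirations flag FEV1 as undefined", {
  prof <- subject_profile(fvc_total = 4, peak_expiratory_flow = 8,
                          peak_inspiratory_flow = 4, expiratory_decay_tau = 0.5)
  fv <- simulate_fvc_flow(prof, sample_rate = 1000, exp_duration = 0.6)
  expect_warning(v <- compute_fvc_vitals(fv$flow, as.list(fv$labels[1, ])),
                 "FEV1")
  expect_true(is.na(v$fev1))
})

test_that("mean tidal volume recovers the profile tidal volume", {
  sess <- quiet_sessions(1, seed = 29, n_fvc = 2, tidal_between = 4,
                         spec = sensor_spec("A", noise_sd = 0, resolution = 0,
                                            offset_range = 0))[[1]]
  tv <- mean_tidal_volume(sess$truth_flow, sess$segment_labels)
  expect_equal(tv, sess$profile$tidal_volume, tolerance = 0.01)
})
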