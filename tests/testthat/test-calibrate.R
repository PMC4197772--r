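test_that("factory models sit at the reference electrophysiological anchors", {
  for (cls in c("I", "II", "III")) {
    model <- get_model(cls)
    st <- steady_state_init(model, settle_ms = 150, dt_ms = 0.02)
    expect_lt(st$drift, 0.5)
    vhold <- steady_voltage(model, -0.1, dt_ms = 0.02)
    expect_equal(vhold, -80, tolerance = 1)
    rin <- (st$v_final - vhold) / 0.1
    expect_equal(rin, 150, tolerance = 150 * 0.05)
  }
})

test_that("rheobase sits at the class target on a 1-s somatic step", {
  # types I and II fire at 0.04 nA and are silent 0.005 nA below it;
  # type III fires at 0.03 nA
  expect_gt(spike_count(get_model("I"), 0.04, dt_ms = 0.02), 0)
  expect_equal(spike_count(get_model("I"), 0.035, dt_ms = 0.02), 0)
  expect_gt(spike_count(get_model("II"), 0.04, dt_ms = 0.02), 0)
  expect_gt(spike_count(get_model("III"), 0.03, dt_ms = 0.02), 0)
  expect_equal(spike_count(get_model("III"), 0.025, dt_ms = 0.02), 0)
})

test_that("the F-I curve rises monotonically from silence", {
  fi <- fi_curve(get_model("I"), c(0, 0.05, 0.1), duration_ms = 600,
                 dt_ms = 0.02)
  expect_equal(fi$rate_hz[1], 0)
  expect_true(all(diff(fi$n_spikes) >= 0))
  expect_gt(fi$rate_hz[3], 0)
  expect_equal(fi$rate_hz, fi$n_spikes / 0.6)
})

test_that("calibration verifies all anchors for the factory type I model", {
  cal <- calibrate_cell("I", refine_rheobase = FALSE, dt_ms = 0.04)
  expect_true(all(cal$report$pass))
})

test_that("terminal dendrites are excitable in every class", {
  for (cls in c("I", "II", "III")) {
    model <- get_model(cls)
    tips <- select_spines(model$morph, "terminal_tip", 4)
    tr <- simulate_cell(model, lapply(tips, synapse_event, onset_ms = 20),
                        recorders = list(sites = recording_sites(model)["trunk_end"],
                                         quantities = "Vm", sample_ms = 0.1),
                        t_end_ms = 150, dt_ms = 0.02)
    expect_gt(nrow(detect_spikes(trace_series(tr, "trunk_end"))), 0)
  }
})
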