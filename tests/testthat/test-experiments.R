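test_that("spike detection interpolates crossings and enforces refractoriness", {
  flat <- data.frame(time_ms = 0:100, value = rep(-65, 101))
  expect_identical(nrow(detect_spikes(flat)), 0L)
  # linear ramp from -10 at t=1 to +10 at t=2 crosses 0 at t=1.5
  ramp <- data.frame(time_ms = c(0, 1, 2, 3), value = c(-65, -10, 10, -65))
  expect_equal(detect_spikes(ramp)$crossing_time_ms, 1.5)
  # triangle wave crossing twice 10 ms apart
  tri <- data.frame(time_ms = seq(0, 30, 0.5),
                    value = -65 + 80 * pmax(0, 1 - abs((seq(0, 30, 0.5) %% 10) - 5) / 4))
  sp <- detect_spikes(tri)
  expect_identical(nrow(sp), 3L)   # crossings near t = 2, 12, 22
  expect_equal(diff(sp$crossing_time_ms), c(10, 10), tolerance = 1e-9)
  # refractory merging of crossings closer than 2 ms
  buzz <- data.frame(time_ms = seq(0, 5, 0.25),
                     value = ifelse(seq(0, 5, 0.25) %% 1 < 0.5, 10, -10))
  expect_true(all(diff(detect_spikes(buzz)$crossing_time_ms) >= 2))
})

test_that("two terminal-tip spines are the somatic spike threshold (type I)", {
  res <- get_min_spines("I", "terminal_tip")
  expect_identical(res$min_spines, 2L)
  expect_true(is.na(res$latencies[1]))
  expect_false(is.na(res$latencies[2]))
  # subthreshold EPSP grows with spine count up to threshold
  expect_gt(res$epsp_peak_mV[1], 0)
})

test_that("deep-dendrite stimulation is rejected for type III", {
  expect_error(min_spines_for_spike(get_model("III"), "deep"),
               "type III granule neuron models have no spines in the deep dendrites")
  expect_error(ap_origin(get_model("III"), "deep"),
               "no spines in the deep dendrites")
})

test_that("magnesium sweep: conductance and EPSP shrink as the block deepens", {
  sw <- mg_sweep(get_model("I"), c(0, 0.12, 1.2), t_end_ms = 400,
                 dt_ms = 0.02)
  expect_true(all(diff(sw$peak_G_NMDA_nS) < 0))
  expect_true(all(diff(sw$epsp_mV) <= 0))
  # magnesium-free peak approaches but does not exceed the channel maximum
  expect_lte(sw$peak_G_NMDA_nS[1], 0.593)
  expect_gt(sw$peak_G_NMDA_nS[1], 0.55)
  # one spine at the reference 1.2 mM: depolarization but no spike
  expect_false(sw$spiked[3])
  expect_gt(sw$epsp_mV[3], 0)
  expect_error(mg_sweep(get_model("I"), c(-1, 1)), "non-negative")
})

test_that("latencies are measured from synapse onset, not run start", {
  model <- get_model("I")
  heads <- select_spines(model$morph, "terminal_tip", 3)
  lat_for_onset <- function(onset) {
    tr <- simulate_cell(model, lapply(heads, synapse_event, onset_ms = onset),
                        recorders = list(sites = recording_sites(model)["soma"],
                                         quantities = "Vm", sample_ms = 0.1),
                        t_end_ms = onset + 150, dt_ms = 0.02)
    first_spike_latency(trace_series(tr, "soma"), onset)
  }
  expect_equal(lat_for_onset(20), lat_for_onset(80), tolerance = 0.05)
})

test_that("type III distal-trunk spines share the trunk threshold of type I", {
  # type III has no proximal-trunk spines; stimulating its distal trunk
  # reproduces the three-spine threshold seen with proximal spines in type I
  expect_identical(get_min_spines("III", "trunk")$min_spines,
                   get_min_spines("I", "trunk")$min_spines)
  expect_identical(get_min_spines("III", "trunk")$min_spines, 3L)
})
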