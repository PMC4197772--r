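test_that("gate variables stay in [0,1] along random voltage trajectories", {
  set.seed(42)
  kin <- default_biophysics("I")$kinetics
  for (rep in 1:5) {
    g <- gate_steady_state(runif(1, -90, -40), kin)
    v <- -65
    for (i in 1:400) {
      v <- min(60, max(-110, v + rnorm(1, 0, 8)))
      g <- gate_step(g, v, dt = runif(1, 0.005, 0.5), kin)
      expect_true(all(g >= 0 & g <= 1))
    }
  }
})

test_that("gates relax exponentially to their steady states", {
  kin <- default_biophysics("I")$kinetics
  g0 <- gate_steady_state(-65, kin)
  expect_equal(gate_step(g0, -65, 0.1, kin), g0, tolerance = 1e-12)
  # long hold at a new potential converges to that steady state
  g <- g0
  for (i in 1:4000) g <- gate_step(g, -30, 1, kin)
  expect_equal(g, gate_steady_state(-30, kin), tolerance = 1e-6)
  # dt -> 0 limit: vanishing change
  expect_equal(gate_step(g0, -30, 1e-9, kin), g0, tolerance = 1e-6)
})

test_that("channel current follows the conductance-based form", {
  g <- gate_steady_state(-40)
  expect_equal(channel_current("na", g, -40, 0, 55), 0)
  expect_equal(channel_current("kdr", g, -90, 500, -90), 0)
  # sign: Na depolarizing below its reversal, K hyperpolarizing above E_K
  expect_gt(channel_current("na", g, -40, 100, 55), 0)
  expect_lt(channel_current("kdr", g, -40, 100, -90), 0)
  expect_error(channel_current("na", c(m = 1.2, h = 0, n = 0, km = 0, kir = 0),
                               -40, 100, 55))
})
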