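test_that("tree solver agrees with a dense-matrix solve on random trees", {
  set.seed(7)
  bp <- passive_biophys()
  for (rep in 1:6) {
    n <- sample(4:12, 1)
    parents <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), 1L))
    tree <- passive_tree(parents, lengths = runif(n, 5, 40),
                         diameters = runif(n, 0.5, 6))
    model <- assemble_cable(tree, bp)
    v0 <- runif(n, -80, -40)
    got <- cable_step(model, v0, dt_ms = 0.05)
    want <- dense_cn_step(tree, bp, v0, dt_ms = 0.05)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)
  }
})

test_that("axial coupling halves when the connecting cylinder doubles", {
  bp <- passive_biophys()
  t1 <- passive_tree(c(NA, 1L), c(10, 10), c(1, 1))
  t2 <- passive_tree(c(NA, 1L), c(20, 20), c(1, 1))
  g1 <- assemble_cable(t1, bp)$arrays$g_ax[2]
  g2 <- assemble_cable(t2, bp)$arrays$g_ax[2]
  expect_equal(g1 / g2, 2, tolerance = 1e-12)
  # two identical coupled compartments: symmetric relaxation to the mean
  m <- assemble_cable(t1, bp)
  v1 <- cable_step(m, c(-60, -70), 0.05)
  expect_equal(v1[1] + v1[2], -130, tolerance = 1e-9)
})

test_that("single-compartment step response matches the RC closed form", {
  bp <- passive_biophys(g_pas = 1, cm = 0.01)   # tau_m = 10 ms
  tree <- passive_tree(NA_integer_, 20, 2)
  model <- assemble_cable(tree, bp)
  area <- pi * 20e-6 * 2e-6
  rin <- 1 / area                      # ohm
  amp <- 0.002                         # nA
  dv_inf <- amp * 1e-9 * rin * 1000    # mV
  tr <- simulate_cell(model, list(current_step(1, amp, 0, 100)),
                      recorders = list(sites = c(c1 = 1), quantities = "Vm",
                                       sample_ms = 1),
                      t_end_ms = 100, dt_ms = 0.1)
  v <- trace_series(tr, "c1")
  exact <- -65 + dv_inf * (1 - exp(-v$time_ms / 10))
  expect_lt(max(abs(v$value - exact)) / dv_inf, 0.001)

  # second-order convergence: error shrinks ~4x per dt halving
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    tr <- simulate_cell(model, list(current_step(1, amp, 0, 100)),
                        recorders = list(sites = c(c1 = 1), quantities = "Vm",
                                         sample_ms = 1),
                        t_end_ms = 100, dt_ms = dt)
    v <- trace_series(tr, "c1")
    max(abs(v$value - (-65 + dv_inf * (1 - exp(-v$time_ms / 10)))))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3); expect_lt(err[1] / err[2], 5)
  expect_gt(err[2] / err[3], 3); expect_lt(err[2] / err[3], 5)
})

test_that("a passive tree at rest stays at rest and decays monotonically", {
  set.seed(11)
  bp <- passive_biophys()
  tree <- passive_tree(c(NA, 1L, 2L, 2L, 1L), runif(5, 10, 30),
                       runif(5, 0.8, 3))
  model <- assemble_cable(tree, bp)
  flat <- simulate_cell(model, list(),
                        recorders = list(sites = c(c1 = 1), quantities = "Vm",
                                         sample_ms = 0.5),
                        t_end_ms = 20, dt_ms = 0.02)
  expect_lt(max(abs(trace_series(flat, "c1")$value + 65)), 1e-11)
  # energy decay from a perturbed state
  tr <- simulate_cell(model, list(),
                      recorders = list(sites = stats::setNames(1:5, paste0("c", 1:5)),
                                       quantities = "Vm", sample_ms = 0.2),
                      t_end_ms = 30, dt_ms = 0.02,
                      v_init_mV = runif(5, -80, -40))
  dev <- sapply(split(abs(tr$value + 65), tr$time_ms), max)
  dev <- dev[order(as.numeric(names(dev)))]
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("simulations are deterministic and validate their inputs", {
  model <- get_model("I")
  heads <- select_spines(model$morph, "terminal_tip", 1)
  pr <- list(synapse_event(heads, 5))
  r1 <- simulate_cell(model, pr, t_end_ms = 20, dt_ms = 0.02)
  r2 <- simulate_cell(model, pr, t_end_ms = 20, dt_ms = 0.02)
  expect_identical(r1, r2)
  expect_error(simulate_cell(model, list(),
                             recorders = list(sites = 1e6, quantities = "Vm",
                                              sample_ms = 0.1),
                             t_end_ms = 1),
               "recorder site")
  expect_error(simulate_cell(model, list(synapse_event(1, 5)), t_end_ms = 1),
               "not a spine head")
})

test_that("steady-state initialization holds the resting potential", {
  st <- steady_state_init(get_model("I"), settle_ms = 200, dt_ms = 0.02)
  expect_lt(st$drift, 0.5)
  expect_equal(st$v_final, -65, tolerance = 0.5)
})

test_that("an exactly clamped spine head reproduces the NMDA I-V endpoints", {
  model <- get_model("I")
  head <- select_spines(model$morph, "terminal_tip", 1)
  vr <- ghk_reversal()
  at_vr <- voltage_clamp_run(model, head, vr, t_end_ms = 400, dt_ms = 0.02)
  expect_lt(abs(at_vr$peak_I_NMDA_nA), 1e-3)
  hyper <- voltage_clamp_run(model, head, -100, t_end_ms = 400, dt_ms = 0.02)
  mid <- voltage_clamp_run(model, head, -20, t_end_ms = 400, dt_ms = 0.02)
  # deep block at -100 mV: little calcium entry; relief at -20 mV
  expect_lt(hyper$peak_Ca_uM - 0.05, 0.2 * (mid$peak_Ca_uM - 0.05))
  expect_gt(mid$peak_I_NMDA_nA, 0)
  none <- voltage_clamp_run(model, head, -65, event = synapse_event(head, 1e6),
                            t_end_ms = 100, dt_ms = 0.02)
  expect_equal(none$peak_Ca_uM, 0.05, tolerance = 1e-9)
  expect_error(voltage_clamp_run(model, 1, -65), "not a spine head")
})
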