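test_that("extended GHK reversal matches an independent flux-balance solve", {
  p <- ghk_params()
  # independent oracle: the reversal potential is where the summed GHK flux
  # of monovalent ions and calcium vanishes; solve numerically
  rtf <- p$gas * p$temperature / p$faraday
  flux <- function(v_mV) {
    u <- v_mV / 1000 / rtf
    mono <- u * (p$monovalent - p$monovalent * exp(-u)) / (1 - exp(-u))
    ca <- 4 * p$perm_ratio * u *
      (-p$ca_out * exp(-2 * u)) / (1 - exp(-2 * u))
    mono + ca
  }
  vr_num <- uniroot(flux, c(0.5, 5), tol = 1e-12)$root
  expect_equal(ghk_reversal(), vr_num, tolerance = 1e-8)
  expect_equal(ghk_reversal(), 2.18919, tolerance = 1e-5)
  # PCa/PM -> 0 collapses to the monovalent Nernst-like zero
  p0 <- ghk_params(perm_ratio = 1e-12)
  expect_equal(ghk_reversal(p0), 0, tolerance = 1e-6)
  # more external calcium pushes the reversal up
  expect_gt(ghk_reversal(ghk_params(ca_out = 4)), ghk_reversal())
})

test_that("fractional calcium current has the reference value and limits", {
  expect_equal(fractional_ca(-65), 0.157535, tolerance = 1e-6)
  # V -> -Inf limit: exponential term vanishes
  p <- ghk_params()
  lim <- p$ca_out / (p$ca_out + p$monovalent / (4 * p$perm_ratio))
  expect_equal(fractional_ca(-1000), lim, tolerance = 1e-9)
  # the calcium-carried fraction grows toward the reversal potential as the
  # monovalent driving force vanishes
  v <- seq(-120, 0, by = 5)
  expect_true(all(diff(fractional_ca(v)) > 0))
  expect_true(all(fractional_ca(seq(-150, 100, 10)) >= 0))
  expect_true(all(fractional_ca(seq(-150, 100, 10)) <= 1))
})

test_that("magnesium block follows its closed formula", {
  # direct evaluation: 1/(1 + 0.2801 * 1.2 * exp(62 * 0.065))
  expect_equal(mg_block(-65, 1.2), 1 / (1 + 0.2801 * 1.2 * exp(62 * 0.065)),
               tolerance = 1e-12)
  expect_equal(mg_block(-65, 1.2), 0.05022, tolerance = 1e-4)
  expect_equal(mg_block(-40, 0), 1.0)
  expect_gt(mg_block(-40, 1.2), mg_block(-80, 1.2))
  v <- seq(-100, 50, 5)
  b <- mg_block(v, 1.2)
  expect_true(all(diff(b) > 0) && all(b > 0) && all(b <= 1))
})

test_that("AMPA conductance is a peak-normalized dual exponential", {
  tstar <- 2 * 5.5 * log(5.5 / 2) / (5.5 - 2)
  expect_equal(tstar, 3.179, tolerance = 1e-3)
  expect_equal(ampa_conductance(tstar), 1.0, tolerance = 1e-12)
  grid <- ampa_conductance(seq(0, 60, by = 0.001))
  expect_equal(max(grid), 1.0, tolerance = 1e-7)
  expect_equal(ampa_conductance(0), 0)
  expect_equal(ampa_conductance(-5), 0)
  expect_lt(ampa_conductance(1000), 1e-12)
  expect_true(all(grid >= 0))
})

test_that("NMDA conductance is blocked below its maximum and ordered in Mg", {
  t <- seq(0.5, 1500, by = 0.5)
  g_rest <- nmda_conductance(t, -65)
  expect_lt(max(g_rest), 0.593)
  g_free <- nmda_conductance(t, -65, nmda_params(mg = 0))
  expect_true(all(g_free > g_rest))
  expect_equal(max(g_free), 0.593, tolerance = 1e-6)
  expect_equal(nmda_conductance(0, -65), 0)
})

test_that("NMDA I-V relation reverses at the GHK potential", {
  vr <- ghk_reversal()
  tstar <- 52 * 343 * log(343 / 52) / (343 - 52)
  iv <- function(v) synaptic_current(nmda_conductance(tstar, v), vr, v)
  expect_equal(iv(vr), 0, tolerance = 1e-12)
  expect_gt(iv(vr - 10), 0)   # inward below reversal
  expect_lt(iv(vr + 10), 0)   # outward above
  # negative slope conductance region at hyperpolarized potentials:
  # inward current grows with depolarization between -80 and -30 mV
  expect_gt(iv(-40), iv(-80))
})

test_that("ohmic synaptic current follows I = G (E - Vm)", {
  expect_equal(synaptic_current(0, 0, -65), 0)
  expect_equal(synaptic_current(2.5, -10, -10), 0)
  expect_equal(synaptic_current(1, 0, -65), 0.065)
  expect_error(synaptic_current(-1, 0, -65))
})

test_that("calcium shell constant matches the reference geometry", {
  expect_equal(compute_shell_constant(2, 0.1, 10), 2.6e12)
  expect_equal(compute_shell_constant(2, 0.1, 1), 2.6e13)
  expect_equal(compute_shell_constant(4, 0.1, 10),
               compute_shell_constant(2, 0.1, 10) / 2)
  expect_error(compute_shell_constant(0, 0.1))
})

test_that("calcium shell dynamics decay to rest and track steady input", {
  st <- ca_shell_params()
  expect_equal(ca_shell_step(0.05, 0, 1, st), 0.05, tolerance = 1e-12)
  # closed-form exponential decay from 1 uM over t = 3/r
  t3 <- 3 / st$extrusion_rate * 1000   # ms
  ca <- 1
  for (i in 1:300) ca <- ca_shell_step(ca, 0, t3 / 300, st)
  expect_equal(ca - 0.05, (1 - 0.05) * exp(-3), tolerance = 1e-6)
  # constant current settles at rest + B I / r
  ica <- 1e-3   # nA
  target <- 0.05 + st$B * ica * 1e-9 * 1e3 / st$extrusion_rate
  ca <- 0.05
  for (i in 1:5000) ca <- ca_shell_step(ca, ica, 0.01, st)
  expect_equal(ca, target, tolerance = 1e-6)
  # never negative, even with strong outward current
  expect_gte(ca_shell_step(0.01, -1, 100, st), 0)
})

test_that("calcium component of the NMDA current scales by Pf", {
  expect_equal(ca_current_into_shell(0, -65), 0)
  expect_equal(ca_current_into_shell(0.1, -65) / 0.1, fractional_ca(-65))
  v <- seq(-120, 60, 10)
  expect_true(all(abs(ca_current_into_shell(0.2, v)) <= 0.2 + 1e-15))
})
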