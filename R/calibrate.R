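#' Somatic membrane potential under a constant current
#'
#' Injects a constant current at the soma from rest and returns the somatic
#' potential at the end of the run (steady state for subthreshold currents).
#'
#' @param model A `granule_model`.
#' @param current_nA Injected current, nA.
#' @param t_end_ms Run length, ms.
#' @param dt_ms Step, ms.
#' @return Somatic membrane potential, mV.
#' @export
steady_voltage <- function(model, current_nA, t_end_ms = 600, dt_ms = 0.02) {
  soma <- recording_sites(model)["soma"]
  tr <- simulate_cell(model,
                      list(current_step(soma, current_nA, 0, t_end_ms)),
                      recorders = list(sites = soma, quantities = "Vm",
                                       sample_ms = 1),
                      t_end_ms = t_end_ms, dt_ms = dt_ms)
  v <- trace_series(tr, "soma")$value
  v[length(v)]
}

#' Count somatic spikes during a current step
#'
#' @param model A `granule_model`.
#' @param current_nA Step amplitude, nA.
#' @param duration_ms Step duration, ms (onset at t = 0).
#' @param dt_ms Step, ms.
#' @return Number of somatic spikes (upward 0 mV crossings).
#' @export
spike_count <- function(model, current_nA, duration_ms = 1000, dt_ms = 0.02) {
  soma <- recording_sites(model)["soma"]
  tr <- simulate_cell(model,
                      list(current_step(soma, current_nA, 0, duration_ms)),
                      recorders = list(sites = soma, quantities = "Vm",
                                       sample_ms = 0.1),
                      t_end_ms = duration_ms, dt_ms = dt_ms)
  nrow(detect_spikes(trace_series(tr, "soma")))
}

#' Rheobase by bisection
#'
#' The minimum constant somatic current step (1 s) that elicits at least
#' one spike, located by bisection to the stated resolution.
#'
#' @param model A `granule_model`.
#' @param lo,hi Bracketing currents, nA (`lo` silent, `hi` spiking; the
#'   bracket is verified and widened upward once if needed).
#' @param resolution Bisection resolution, nA.
#' @param duration_ms Step duration, ms.
#' @param dt_ms Step, ms.
#' @return Rheobase estimate (smallest tested spiking current), nA.
#' @export
find_rheobase <- function(model, lo = 0.005, hi = 0.2, resolution = 0.005,
                          duration_ms = 1000, dt_ms = 0.02) {
  if (spike_count(model, lo, duration_ms, dt_ms) > 0)
    stop("lower bracket ", lo, " nA already spikes")
  if (spike_count(model, hi, duration_ms, dt_ms) == 0) {
    hi <- hi * 2
    if (spike_count(model, hi, duration_ms, dt_ms) == 0)
      stop("upper bracket ", hi, " nA does not spike")
  }
  while (hi - lo > resolution + 1e-12) {
    mid <- round((hi + lo) / 2 / resolution) * resolution
    if (mid <= lo || mid >= hi) break
    if (spike_count(model, mid, duration_ms, dt_ms) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Calibrate a granule cell model against the reference anchors
#'
#' Fixes the free passive and channel-density parameters against the
#' electrophysiological anchors: (1) quiescent somatic potential -65 mV
#' (enforced exactly by the leak-reversal solve, verified by free run);
#' (2) a -0.1 nA somatic step settles at -80 mV, i.e. a 150 Mohm chord
#' input resistance (leak density bisection); (3) rheobase equal to the
#' class target on a 1-s somatic step at 0.005 nA resolution (Na-density
#' scale bisection over the soma and trunk Na densities); (4) terminal
#' dendrites remain excitable (synaptic activation of all terminal-tip
#' spines elicits a regenerative dendritic spike).
#'
#' The package ships with the result of this procedure as the factory
#' densities in [default_biophysics()]; rerunning it reproduces them.
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @param targets A [calibration_targets()] list.
#' @param biophys Starting biophysics.
#' @param dt_ms Integration step used during the search, ms.
#' @param refine_rheobase If `FALSE`, skip the (slow) rheobase bisection
#'   and only verify the other anchors.
#' @return List with `biophys` (calibrated), and `report`, a data frame of
#'   constraint/value/target/pass rows. If a constraint cannot be
#'   satisfied, the report row has `pass = FALSE` (no error is thrown).
#' @export
calibrate_cell <- function(cell_class,
                           targets = calibration_targets(cell_class),
                           biophys = default_biophysics(cell_class),
                           dt_ms = 0.02, refine_rheobase = TRUE) {
  morph <- build_morphology(cell_class)

  remodel <- function(bp) assemble_cable(morph, bp)

  # (2) leak density: bisect so that -0.1 nA settles at the hold target
  vtar <- targets$hyperpol_hold$v_target
  f <- function(g) {
    bp <- biophys; bp$passive$g_pas <- g
    steady_voltage(remodel(bp), targets$hyperpol_hold$current, dt_ms = dt_ms)
  }
  lo <- 0.4; hi <- 8
  v_lo <- f(lo); v_hi <- f(hi)
  if ((v_lo - vtar) * (v_hi - vtar) < 0) {
    for (it in 1:28) {
      mid <- (lo + hi) / 2
      v_mid <- f(mid)
      if ((v_lo - vtar) * (v_mid - vtar) <= 0) { hi <- mid; v_hi <- v_mid }
      else { lo <- mid; v_lo <- v_mid }
      if (hi - lo < 1e-3) break
    }
    biophys$passive$g_pas <- (lo + hi) / 2
  }
  model <- remodel(biophys)

  # (3) rheobase: bisect a common Na-density scale
  if (refine_rheobase) {
    rheo_of <- function(s) {
      bp <- biophys
      for (r in c("soma", "trunk_proximal", "trunk_distal"))
        bp$densities[[r]][["na"]] <- bp$densities[[r]][["na"]] * s
      find_rheobase(remodel(bp), dt_ms = dt_ms)
    }
    r0 <- rheo_of(1)
    if (abs(r0 - targets$rheobase) > 0.005 / 2) {
      slo <- 0.5; shi <- 2.0; s <- NA
      for (it in 1:14) {
        smid <- sqrt(slo * shi)
        rm <- rheo_of(smid)
        if (abs(rm - targets$rheobase) <= 0.005 / 2) { s <- smid; break }
        if (rm > targets$rheobase) slo <- smid else shi <- smid
        if (shi / slo < 1.004) break
      }
      if (is.na(s)) s <- sqrt(slo * shi)
      for (r in c("soma", "trunk_proximal", "trunk_distal"))
        biophys$densities[[r]][["na"]] <- biophys$densities[[r]][["na"]] * s
      model <- remodel(biophys)
    }
  }

  # verification
  rest <- steady_state_init(model, dt_ms = dt_ms)
  vhold <- steady_voltage(model, targets$hyperpol_hold$current, dt_ms = dt_ms)
  rin <- (rest$v_final - vhold) / abs(targets$hyperpol_hold$current)
  rheo <- find_rheobase(model, dt_ms = dt_ms)
  sub <- spike_count(model, targets$rheobase - 0.005, dt_ms = dt_ms)
  tips <- select_spines(morph, "terminal_tip",
                        morph$params$terminal_branches[["tip"]])
  tr <- simulate_cell(model, lapply(tips, synapse_event, onset_ms = 50),
                      recorders = list(sites = recording_sites(model)["trunk_end"],
                                       quantities = "Vm", sample_ms = 0.1),
                      t_end_ms = 300, dt_ms = dt_ms)
  dend_spike <- nrow(detect_spikes(trace_series(tr, "trunk_end"))) > 0

  report <- data.frame(
    constraint = c("resting potential (mV)", "hold at -0.1 nA (mV)",
                   "input resistance (Mohm)", "rheobase (nA)",
                   "silent below rheobase", "terminal dendrites excitable"),
    value = c(rest$v_final, vhold, rin, rheo, sub == 0, dend_spike),
    target = c(targets$v_rest, vtar, targets$input_resistance,
               targets$rheobase, TRUE, TRUE),
    pass = c(abs(rest$v_final - targets$v_rest) <= 0.5,
             abs(vhold - vtar) <= 1,
             abs(rin - targets$input_resistance) <=
               0.05 * targets$input_resistance,
             abs(rheo - targets$rheobase) <= 0.005 / 2,
             sub == 0, dend_spike))
  list(biophys = biophys, report = report)
}

#' F-I curve of a calibrated model
#'
#' Spike rate against injected somatic current (1-s steps by default). The
#' three calibrated classes produce closely similar, monotonically rising
#' curves above rheobase.
#'
#' @param model A `granule_model`.
#' @param currents Currents, nA, sorted ascending.
#' @param duration_ms Step duration, ms.
#' @param dt_ms Step, ms.
#' @return Data frame with current_nA, n_spikes, rate_hz.
#' @export
fi_curve <- function(model, currents, duration_ms = 1000, dt_ms = 0.02) {
  stopifnot(!is.unsorted(currents))
  n <- vapply(currents, function(a)
    spike_count(model, a, duration_ms, dt_ms), numeric(1))
  data.frame(current_nA = currents, n_spikes = n,
             rate_hz = n / (duration_ms / 1000))
}
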