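#' Detect spikes as threshold crossings
#'
#' One spike per upward crossing of the detection threshold, with a 2 ms
#' refractory separation; the crossing time is linearly interpolated
#' between samples.
#'
#' @param trace Data frame with columns time_ms and value (a Vm series), as
#'   returned by [trace_series()].
#' @param threshold_mV Detection threshold, mV.
#' @param refractory_ms Minimum separation between events, ms.
#' @return Data frame with one row per spike: crossing_time_ms.
#' @export
detect_spikes <- function(trace, threshold_mV = 0, refractory_ms = 2) {
  t <- trace$time_ms; v <- trace$value
  up <- which(v[-length(v)] < threshold_mV & v[-1] >= threshold_mV)
  if (!length(up))
    return(data.frame(crossing_time_ms = numeric(0)))
  frac <- (threshold_mV - v[up]) / (v[up + 1] - v[up])
  times <- t[up] + frac * (t[up + 1] - t[up])
  keep <- c(TRUE, diff(times) >= refractory_ms)
  # greedy refractory: re-filter until stable (events removed can expose
  # later ones that are now too close to the previous kept event)
  times <- times[keep]
  if (length(times) > 1) {
    out <- times[1]
    for (x in times[-1]) if (x - out[length(out)] >= refractory_ms)
      out <- c(out, x)
    times <- out
  }
  data.frame(crossing_time_ms = times)
}

#' First threshold-crossing latency
#'
#' @param trace Vm series data frame.
#' @param onset_ms Stimulus onset; latency is measured from it.
#' @param threshold_mV Threshold, mV.
#' @return Latency in ms, or `NA` if no crossing.
#' @export
first_spike_latency <- function(trace, onset_ms, threshold_mV = 0) {
  sp <- detect_spikes(trace, threshold_mV)
  if (!nrow(sp)) return(NA_real_)
  sp$crossing_time_ms[1] - onset_ms
}

.as_model <- function(x) {
  if (inherits(x, "granule_model")) x else granule_model(x)
}

.location_max_n <- function(model, location) {
  p <- model$morph$params
  switch(location,
    terminal_tip = p$terminal_branches[["tip"]],
    trunk = nrow(model$morph$spines[
      model$morph$compartments$region[model$morph$spines$parent_id] == "trunk", ]),
    deep = p$n_deep_branches)
}

#' Minimum number of activated spines for a somatic spike
#'
#' Activates n = 1..n_max spines simultaneously at a dendritic location
#' (terminal tips on distinct branches, trunk spines outward from the
#' soma, or deep-dendrite tips) and finds the smallest n that elicits a
#' somatic action potential, together with the first-spike latency for
#' every spiking n.
#'
#' @param cell A `granule_model` or a class label.
#' @param location One of `"terminal_tip"`, `"trunk"`, `"deep"`.
#' @param n_max Largest spine count tested (default: all branches/spines
#'   available at the location, capped at 4).
#' @param t_end_ms Trial length, ms.
#' @param onset_ms Synaptic onset, ms.
#' @param dt_ms Step, ms.
#' @return A `min_spine_result`: list with cell_class, location,
#'   min_spines (integer or NA if not reached), and latencies (named map
#'   n -> first-spike latency ms, NA when subthreshold), plus the somatic
#'   EPSP peak per n.
#' @export
min_spines_for_spike <- function(cell, location = c("terminal_tip", "trunk", "deep"),
                                 n_max = NULL, t_end_ms = 500, onset_ms = 50,
                                 dt_ms = 0.01) {
  location <- match.arg(location)
  model <- .as_model(cell)
  if (location == "deep" && model$morph$cell_class == "III")
    stop("type III granule neuron models have no spines in the deep dendrites")
  if (is.null(n_max)) n_max <- min(4L, .location_max_n(model, location))
  soma <- recording_sites(model)["soma"]
  latencies <- epsp <- stats::setNames(rep(NA_real_, n_max), seq_len(n_max))
  min_spines <- NA_integer_
  for (n in seq_len(n_max)) {
    heads <- select_spines(model$morph, location, n)
    tr <- simulate_cell(model, lapply(heads, synapse_event, onset_ms = onset_ms),
                        recorders = list(sites = soma, quantities = "Vm",
                                         sample_ms = 0.1),
                        t_end_ms = t_end_ms, dt_ms = dt_ms)
    v <- trace_series(tr, "soma")
    latencies[n] <- first_spike_latency(v, onset_ms)
    epsp[n] <- max(v$value) - v$value[1]
    if (is.na(min_spines) && !is.na(latencies[n])) min_spines <- n
  }
  structure(list(cell_class = model$morph$cell_class, location = location,
                 min_spines = min_spines, latencies = latencies,
                 epsp_peak_mV = epsp),
            class = "min_spine_result")
}

#' @export
print.min_spine_result <- function(x, ...) {
  cat("Minimum activated spines for a somatic spike, type ", x$cell_class,
      ", ", x$location, ": ",
      if (is.na(x$min_spines)) "not reached" else x$min_spines, "\n",
      sep = "")
  invisible(x)
}

#' Determine the initiation site of the action potential
#'
#' Runs a synaptic stimulation and compares the first 0 mV crossing at the
#' distal-trunk recording site ("terminal region of the trunk") with the
#' somatic one. The origin is the dendrite when the trunk crosses first,
#' the soma when the soma crosses first, and none when neither crosses.
#' The crossing at a terminal-branch midpoint is reported as well.
#'
#' @param cell A `granule_model` or class label.
#' @param location Stimulation location (see [min_spines_for_spike()]).
#' @param n_spines Number of activated spines (default: one per branch at
#'   the location).
#' @param t_end_ms,onset_ms,dt_ms Simulation controls.
#' @return An `origin_result`: list with trunk_crossing_ms,
#'   soma_crossing_ms, terminal_crossing_ms (NA when subthreshold) and
#'   origin in {"dendrite", "soma", "none"}.
#' @export
ap_origin <- function(cell, location = c("terminal_tip", "trunk", "deep"),
                      n_spines = NULL, t_end_ms = 500, onset_ms = 50,
                      dt_ms = 0.01) {
  location <- match.arg(location)
  model <- .as_model(cell)
  if (location == "deep" && model$morph$cell_class == "III")
    stop("type III granule neuron models have no spines in the deep dendrites")
  if (is.null(n_spines))
    n_spines <- if (location == "trunk") 3L else .location_max_n(model, location)
  heads <- select_spines(model$morph, location, n_spines)
  sites <- recording_sites(model)
  tr <- simulate_cell(model, lapply(heads, synapse_event, onset_ms = onset_ms),
                      recorders = list(sites = sites, quantities = "Vm",
                                       sample_ms = 0.1),
                      t_end_ms = t_end_ms, dt_ms = dt_ms)
  cross <- function(site) {
    sp <- detect_spikes(trace_series(tr, site))
    if (nrow(sp)) sp$crossing_time_ms[1] else NA_real_
  }
  trunk <- cross("trunk_end"); soma <- cross("soma"); term <- cross("terminal_mid")
  origin <- if (is.na(trunk) && is.na(soma)) "none"
            else if (!is.na(trunk) && (is.na(soma) || trunk < soma)) "dendrite"
            else "soma"
  structure(list(cell_class = model$morph$cell_class, location = location,
                 n_spines = n_spines, trunk_crossing_ms = trunk,
                 soma_crossing_ms = soma, terminal_crossing_ms = term,
                 origin = origin, traces = tr),
            class = "origin_result")
}

#' @export
print.origin_result <- function(x, ...) {
  cat("AP origin, type ", x$cell_class, ", ", x$location, " x", x$n_spines,
      " spines: ", x$origin,
      if (x$origin != "none")
        sprintf(" (trunk %.2f ms, soma %.2f ms)", x$trunk_crossing_ms,
                x$soma_crossing_ms) else "",
      "\n", sep = "")
  invisible(x)
}

#' Tangential-plane stimulation of the terminal dendrites (type I)
#'
#' Emulates a mitral/tufted secondary dendrite crossing the terminal field
#' tangentially: all spines intersected by a horizontal plane are activated
#' together -- 4 spines at the tip, 3 at the middle, 2 at the base of the
#' terminal field. Optionally a hyperpolarizing current (-0.1 nA) holds the
#' soma near -80 mV to suppress action potentials, exposing the pure EPSP.
#'
#' @param cell A type I `granule_model` or the label `"I"`.
#' @param plane One of `"tip"`, `"middle"`, `"base"`.
#' @param hold_current_nA 0 or -0.1 nA at the soma.
#' @param t_end_ms,onset_ms,dt_ms Simulation controls (onset late enough
#'   for the hold to settle).
#' @return List with plane, n_spines, origin (an `origin_result`-style
#'   label), baseline and peak depolarization (mV, relative to the
#'   pre-stimulus baseline) at the trunk recording site and soma, and the
#'   traces.
#' @export
tangential_stimulation <- function(cell = "I", plane = c("tip", "middle", "base"),
                                   hold_current_nA = 0, t_end_ms = 600,
                                   onset_ms = 200, dt_ms = 0.01) {
  plane <- match.arg(plane)
  model <- .as_model(cell)
  if (model$morph$cell_class != "I")
    stop("tangential-plane stimulation is defined for the type I model")
  loc <- switch(plane, tip = "terminal_tip", middle = "terminal_middle",
                base = "terminal_base")
  n <- switch(plane, tip = 4L, middle = 3L, base = 2L)
  heads <- select_spines(model$morph, loc, n)
  sites <- recording_sites(model)
  protocol <- lapply(heads, synapse_event, onset_ms = onset_ms)
  if (hold_current_nA != 0)
    protocol <- c(protocol, list(current_step(sites[["soma"]], hold_current_nA,
                                              0, t_end_ms)))
  tr <- simulate_cell(model, protocol,
                      recorders = list(sites = sites, quantities = "Vm",
                                       sample_ms = 0.1),
                      t_end_ms = t_end_ms, dt_ms = dt_ms)
  peak_rel <- function(site) {
    v <- trace_series(tr, site)
    base <- v$value[max(which(v$time_ms <= onset_ms))]
    c(baseline = base, peak = max(v$value[v$time_ms > onset_ms]) - base)
  }
  trunk <- peak_rel("trunk_end"); soma <- peak_rel("soma")
  cross <- function(site) {
    sp <- detect_spikes(trace_series(tr, site))
    if (nrow(sp)) sp$crossing_time_ms[1] else NA_real_
  }
  tcx <- cross("trunk_end"); scx <- cross("soma")
  origin <- if (is.na(tcx) && is.na(scx)) "none"
            else if (!is.na(tcx) && (is.na(scx) || tcx < scx)) "dendrite"
            else "soma"
  list(plane = plane, n_spines = n, hold_current_nA = hold_current_nA,
       origin = origin,
       baseline_mV = c(trunk = trunk[["baseline"]], soma = soma[["baseline"]]),
       peak_depol_mV = c(trunk = trunk[["peak"]], soma = soma[["peak"]]),
       spiked = !is.na(scx), traces = tr)
}

#' Magnesium sweep on a single terminal-tip spine
#'
#' Activates one spine at the tip of a terminal dendrite under different
#' extracellular magnesium concentrations and reports the peak NMDA
#' conductance at the spine and the somatic EPSP amplitude. Both decrease
#' monotonically with magnesium as the block deepens.
#'
#' @param cell A type I `granule_model` or class label.
#' @param mg_levels Magnesium concentrations, mM.
#' @param t_end_ms,onset_ms,dt_ms Simulation controls.
#' @return Data frame: mg_mM, peak_G_NMDA_nS, epsp_mV, spiked.
#' @export
mg_sweep <- function(cell = "I", mg_levels = c(0, 0.012, 0.12, 1.2, 2.4),
                     t_end_ms = 600, onset_ms = 50, dt_ms = 0.01) {
  if (any(mg_levels < 0)) stop("magnesium concentrations must be non-negative")
  model <- .as_model(cell)
  head <- select_spines(model$morph, "terminal_tip", 1)
  soma <- recording_sites(model)["soma"]
  out <- lapply(mg_levels, function(mg) {
    m <- model
    m$arrays$syn$mg <- mg
    m$biophys$synapse$nmda$mg <- mg
    tr <- simulate_cell(m, list(synapse_event(head, onset_ms)),
                        recorders = list(sites = c(soma, head = head),
                                         quantities = c("Vm", "G_NMDA"),
                                         sample_ms = 0.1),
                        t_end_ms = t_end_ms, dt_ms = dt_ms)
    v <- trace_series(tr, "soma", "Vm")
    data.frame(mg_mM = mg,
               peak_G_NMDA_nS = max(trace_series(tr, "head", "G_NMDA")$value),
               epsp_mV = max(v$value) - v$value[1],
               spiked = nrow(detect_spikes(v)) > 0)
  })
  do.call(rbind, out)
}

#' First-spike latency against number of activated spines
#'
#' @param cell A `granule_model` or class label.
#' @param location Stimulation location.
#' @param ... Passed to [min_spines_for_spike()].
#' @return Data frame n_spines / latency_ms (NA below threshold).
#' @export
latency_vs_nspines <- function(cell, location = c("terminal_tip", "trunk", "deep"),
                               ...) {
  res <- min_spines_for_spike(cell, location, ...)
  data.frame(n_spines = as.integer(names(res$latencies)),
             latency_ms = unname(res$latencies))
}
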