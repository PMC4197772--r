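#' Assemble the cable system for a morphology
#'
#' Converts a `granule_morphology` plus biophysical parameters into the
#' arrays the implicit solver consumes: per-compartment capacitance, leak
#' and maximal channel conductances (density times membrane area, including
#' the missing-spine area correction), and the axial coupling conductance
#' of every parent-child pair (series sum of the two half-cylinder axial
#' resistances). Compartments are ordered parent-before-child so the
#' implicit solve is a single O(N) Hines sweep. The leak reversal of each
#' compartment is solved so that the quiescent cell is exactly at the
#' resting potential: e_pas = V0 - sum_ch g_ch(V0) (E_ch - V0) / g_pas.
#'
#' @param morph A `granule_morphology` (with or without spines).
#' @param biophys A [default_biophysics()] list.
#' @return A `granule_model` object wrapping the morphology, parameters and
#'   solver arrays.
#' @export
assemble_cable <- function(morph, biophys = default_biophysics(morph$cell_class)) {
  stopifnot(inherits(morph, "granule_morphology"))
  validate_morphology(morph)
  comp <- morph$compartments
  n <- nrow(comp)
  parent <- comp$parent_id
  if (any(stats::na.omit(parent) >= comp$id[!is.na(parent)]))
    stop("compartments must be ordered parent before child")

  area <- (pi * comp$diameter * comp$length + comp$extra_area) * 1e-12  # m^2
  cm_v <- biophys$passive$cm * area
  g_pas <- biophys$passive$g_pas * area

  dkey <- comp$region
  zoned <- dkey %in% c("terminal", "trunk") &
    paste0(dkey, "_", comp$zone) %in% names(biophys$densities)
  dkey[zoned] <- paste0(dkey[zoned], "_", comp$zone[zoned])
  dens <- t(vapply(dkey, function(r) {
    if (r %in% names(biophys$densities)) biophys$densities[[r]]
    else c(na = 0, kdr = 0, km = 0, kir = 0)
  }, numeric(4)))
  gbar <- dens * area

  # axial coupling: half-cylinder resistances in series
  ra <- biophys$passive$ra
  half_res <- ra * (comp$length * 1e-6 / 2) / (pi * (comp$diameter * 1e-6 / 2)^2)
  g_ax <- numeric(n)
  has_par <- !is.na(parent)
  g_ax[has_par] <- 1 / (half_res[has_par] + half_res[parent[has_par]])

  # leak reversal fixing V0 as the quiescent fixed point
  v0 <- biophys$v_rest
  gates <- gate_tables(v0, biophys$kinetics)[1, ]
  open <- c(na = gates[["m_inf"]]^3 * gates[["h_inf"]],
            kdr = gates[["n_inf"]]^4, km = gates[["km_inf"]],
            kir = gates[["kir_inf"]])
  erev <- c(na = biophys$reversals[["na"]], kdr = biophys$reversals[["k"]],
            km = biophys$reversals[["k"]], kir = biophys$reversals[["k"]])
  chan_bal <- dens %*% (open * (erev - v0)) # (S/m^2) * mV
  e_pas <- v0 - as.numeric(chan_bal) / biophys$passive$g_pas

  syn <- biophys$synapse
  arrays <- list(
    parent = as.integer(ifelse(is.na(parent), -1L, parent - 1L)),
    cm = cm_v, g_pas = g_pas, e_pas = e_pas / 1000,
    g_ax = g_ax, gbar = gbar,
    ena = biophys$reversals[["na"]] / 1000,
    ek = biophys$reversals[["k"]] / 1000,
    kin = biophys$kinetics,
    syn = list(
      a_gmax = syn$ampa$g_max * 1e-9, a_tau1 = syn$ampa$tau1 / 1000,
      a_tau2 = syn$ampa$tau2 / 1000, a_E = syn$ampa$reversal / 1000,
      n_gmax = syn$nmda$g_max * 1e-9, n_tau1 = syn$nmda$tau1 / 1000,
      n_tau2 = syn$nmda$tau2 / 1000, n_E = syn$nmda$reversal / 1000,
      eta = syn$nmda$eta, mg = syn$nmda$mg, gamma = syn$nmda$gamma),
    shell = list(B = syn$shell$B, r = syn$shell$extrusion_rate,
                 ca_rest = syn$shell$ca_rest),
    ghk = list(cao = syn$ghk$ca_out, monovalent = syn$ghk$monovalent,
               pratio = syn$ghk$perm_ratio, temperature = syn$ghk$temperature,
               faraday = syn$ghk$faraday, gas = syn$ghk$gas)
  )
  structure(list(morph = morph, biophys = biophys, arrays = arrays),
            class = "granule_model")
}

#' Build a ready-to-simulate granule cell model
#'
#' Convenience constructor: builds the morphology (spines placed,
#' missing-spine area correction applied) and assembles the cable system
#' with the class's calibrated biophysics.
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @param biophys Biophysical parameter list.
#' @param geometry_overrides Passed to [build_cell()].
#' @return A `granule_model`.
#' @export
granule_model <- function(cell_class, biophys = default_biophysics(cell_class),
                          geometry_overrides = NULL) {
  assemble_cable(build_morphology(cell_class, geometry_overrides), biophys)
}

#' @export
print.granule_model <- function(x, ...) {
  cat("Calibrated granule cell model (type ", x$morph$cell_class, "), ",
      nrow(x$morph$compartments), " total compartments (",
      nrow(x$morph$spines), " spines)\n", sep = "")
  invisible(x)
}

#' Named recording sites of a model
#'
#' `soma` is the root compartment; `trunk_end` the most distal trunk
#' compartment (the "terminal region of the trunk" used to detect dendritic
#' spike initiation); `terminal_mid` the midpoint of the first middle-zone
#' terminal branch.
#'
#' @param model A `granule_model`.
#' @return Named integer vector of compartment ids.
#' @export
recording_sites <- function(model) {
  comp <- model$morph$compartments
  trunk <- comp[comp$region == "trunk", ]
  mid <- comp[comp$region == "terminal" & comp$zone == "middle" &
                comp$branch == 1L, ]
  c(soma = comp$id[comp$region == "soma"],
    trunk_end = trunk$id[which.max(trunk$seg)],
    terminal_mid = mid$id[mid$seg == ceiling(max(mid$seg) / 2)])
}

#' Protocol element constructors
#'
#' `current_step()` injects a constant current at a compartment over a time
#' window; `voltage_clamp()` holds a compartment exactly at a level (row
#' replacement in the implicit system, no clamp-gain parameter);
#' `synapse_event()` activates the AMPA + NMDA synapse of a spine head at
#' an onset time. Repeat events on the same head sum linearly.
#'
#' @param site Compartment id.
#' @param amplitude_nA Injected current, nA.
#' @param level_mV Clamp level, mV.
#' @param head_id Spine head compartment id.
#' @param onset_ms,offset_ms Window, ms.
#' @return A protocol element (tagged list).
#' @name protocol
NULL

#' @rdname protocol
#' @export
current_step <- function(site, amplitude_nA, onset_ms, offset_ms) {
  stopifnot(offset_ms > onset_ms)
  list(kind = "iclamp", site = site, amp = amplitude_nA,
       on = onset_ms, off = offset_ms)
}

#' @rdname protocol
#' @export
voltage_clamp <- function(site, level_mV, onset_ms, offset_ms) {
  stopifnot(offset_ms > onset_ms)
  list(kind = "vclamp", site = site, level = level_mV,
       on = onset_ms, off = offset_ms)
}

#' @rdname protocol
#' @export
synapse_event <- function(head_id, onset_ms) {
  stopifnot(onset_ms >= 0)
  list(kind = "synapse", site = head_id, on = onset_ms)
}

.build_protocol <- function(model, protocol) {
  n <- nrow(model$morph$compartments)
  icl <- matrix(numeric(0), 0, 4)
  vcl <- matrix(numeric(0), 0, 4)
  heads <- integer(0); onsets <- numeric(0)
  for (el in protocol) {
    if (!is.list(el) || is.null(el$kind)) stop("invalid protocol element")
    if (el$site < 1 || el$site > n) stop("protocol site ", el$site,
                                         " not in the tree")
    if (el$kind == "iclamp") {
      icl <- rbind(icl, c(el$site - 1, el$amp * 1e-9, el$on / 1000,
                          el$off / 1000))
    } else if (el$kind == "vclamp") {
      vcl <- rbind(vcl, c(el$site - 1, el$level / 1000, el$on / 1000,
                          el$off / 1000))
    } else if (el$kind == "synapse") {
      if (!el$site %in% model$morph$spines$head_id)
        stop("synapse site ", el$site, " is not a spine head")
      heads <- c(heads, el$site); onsets <- c(onsets, el$on / 1000)
    } else stop("unknown protocol element kind: ", el$kind)
  }
  uh <- sort(unique(heads))
  ev <- if (length(heads))
    cbind(match(heads, uh) - 1L, onsets) else matrix(numeric(0), 0, 2)
  list(iclamp = icl, vclamp = vcl, syn_heads = as.integer(uh - 1L), events = ev)
}

#' Run a simulation
#'
#' Integrates the full model (voltages, gates, synapses, shell calcium)
#' with the Crank-Nicolson scheme and returns the requested recordings as a
#' long trace table. Fully deterministic: identical inputs produce
#' identical traces.
#'
#' @param model A `granule_model`.
#' @param protocol List of protocol elements ([current_step()],
#'   [voltage_clamp()], [synapse_event()]); may be empty.
#' @param recorders List with `sites` (named or plain compartment ids),
#'   `quantities` (subset of Vm, G_AMPA, G_NMDA, I_NMDA, Ca) and
#'   `sample_ms`.
#' @param t_end_ms Simulation length, ms.
#' @param dt_ms Time step, ms (default 0.01 ms = 10 us).
#' @param v_init_mV Initial potential, scalar or per-compartment vector;
#'   gates start at their steady states for it.
#' @return A data frame (`granule_traces`) with columns time_ms, site,
#'   quantity, value.
#' @export
simulate_cell <- function(model, protocol = list(),
                          recorders = list(sites = recording_sites(model)[1],
                                           quantities = "Vm", sample_ms = 0.1),
                          t_end_ms = 500, dt_ms = 0.01,
                          v_init_mV = model$biophys$v_rest) {
  stopifnot(inherits(model, "granule_model"), dt_ms > 0, t_end_ms > 0)
  n <- nrow(model$morph$compartments)
  sites <- recorders$sites
  if (any(sites < 1 | sites > n))
    stop("recorder site outside the tree")
  if (is.null(names(sites))) names(sites) <- paste0("c", sites)
  sample_ms <- if (is.null(recorders$sample_ms)) 0.1 else recorders$sample_ms
  sample_every <- max(1L, as.integer(round(sample_ms / dt_ms)))
  pr <- .build_protocol(model, protocol)
  arr <- model$arrays
  arr$syn_heads <- pr$syn_heads
  arr$events <- pr$events
  vi <- rep_len(v_init_mV, n)
  out <- cpp_simulate(arr, list(iclamp = pr$iclamp, vclamp = pr$vclamp),
                      list(sites = as.integer(sites - 1L),
                           quantities = recorders$quantities,
                           sample_every = sample_every),
                      dt_ms, t_end_ms, vi)
  nq <- length(recorders$quantities)
  traces <- data.frame(
    time_ms = rep(out$time_ms, times = length(sites) * nq),
    site = rep(names(sites), each = length(out$time_ms) * nq),
    quantity = rep(rep(recorders$quantities, each = length(out$time_ms)),
                   times = length(sites)),
    value = as.numeric(out$data),
    stringsAsFactors = FALSE)
  class(traces) <- c("granule_traces", "data.frame")
  traces
}

#' Extract one recorded series from a trace table
#'
#' @param traces A `granule_traces` table.
#' @param site Site name.
#' @param quantity Quantity name.
#' @return Data frame with time_ms and value.
#' @export
trace_series <- function(traces, site, quantity = "Vm") {
  out <- traces[traces$site == site & traces$quantity == quantity,
                c("time_ms", "value")]
  if (!nrow(out)) stop("no recorded series for site '", site,
                       "', quantity '", quantity, "'")
  rownames(out) <- NULL
  out
}

#' Advance a membrane-potential state by one implicit step
#'
#' Single Crank-Nicolson step from an arbitrary per-compartment voltage
#' state (gates at steady state for those voltages). Used for solver
#' verification against a dense-matrix reference.
#'
#' @param model A `granule_model`.
#' @param v_mV Per-compartment potentials, mV.
#' @param dt_ms Step, ms.
#' @return Potentials after one step, mV.
#' @export
cable_step <- function(model, v_mV, dt_ms) {
  tr <- simulate_cell(model, list(),
                      recorders = list(sites = seq_len(nrow(model$morph$compartments)),
                                       quantities = "Vm", sample_ms = dt_ms),
                      t_end_ms = dt_ms, dt_ms = dt_ms, v_init_mV = v_mV)
  tr$value[tr$time_ms > 0][order(as.integer(sub("^c", "",
    tr$site[tr$time_ms > 0])))]
}

#' Initialize at a holding potential and verify stability
#'
#' Sets every compartment to `V0` with gates at steady state, runs the
#' model freely for `settle_ms`, and reports the somatic drift. The
#' calibrated models drift by less than 0.5 mV from the -65 mV resting
#' potential.
#'
#' @param model A `granule_model`.
#' @param V0 Holding potential, mV.
#' @param settle_ms Free-run duration, ms.
#' @param dt_ms Step, ms.
#' @return List with `v_init`, `v_final` (somatic, mV) and `drift` (mV).
#' @export
steady_state_init <- function(model, V0 = model$biophys$v_rest,
                              settle_ms = 200, dt_ms = 0.01) {
  tr <- simulate_cell(model, list(),
                      recorders = list(sites = recording_sites(model)["soma"],
                                       quantities = "Vm", sample_ms = 1),
                      t_end_ms = settle_ms, dt_ms = dt_ms, v_init_mV = V0)
  v <- trace_series(tr, "soma")
  list(v_init = V0, v_final = v$value[nrow(v)],
       drift = abs(v$value[nrow(v)] - V0))
}

#' Voltage-clamp a spine head and measure NMDA current and shell calcium
#'
#' Holds a spine head exactly at a level for the whole run, delivers one
#' synaptic activation, and reports the NMDA current extremum (signed;
#' inward positive) and the peak shell calcium. Sweeping the level maps the
#' NMDA I-V relation: zero crossing at the GHK reversal potential, with the
#' characteristic negative-slope region at hyperpolarized levels where the
#' magnesium block dominates.
#'
#' @param model A `granule_model`.
#' @param site A spine head compartment id.
#' @param level_mV Clamp level, mV.
#' @param event A [synapse_event()] (default onset 50 ms); `NULL` for none.
#' @param t_end_ms Run length, ms.
#' @param dt_ms Step, ms.
#' @return List with `level_mV`, `peak_I_NMDA_nA`, `peak_Ca_uM`.
#' @export
voltage_clamp_run <- function(model, site, level_mV, event = NULL,
                              t_end_ms = 550, dt_ms = 0.01) {
  if (!site %in% model$morph$spines$head_id)
    stop("clamp site ", site, " is not a spine head")
  if (is.null(event)) event <- synapse_event(site, 50)
  protocol <- list(voltage_clamp(site, level_mV, 0, t_end_ms + 1), event)
  tr <- simulate_cell(model, protocol,
                      recorders = list(sites = c(head = site),
                                       quantities = c("I_NMDA", "Ca"),
                                       sample_ms = 0.1),
                      t_end_ms = t_end_ms, dt_ms = dt_ms)
  i_nmda <- trace_series(tr, "head", "I_NMDA")$value
  ca <- trace_series(tr, "head", "Ca")$value
  list(level_mV = level_mV,
       peak_I_NMDA_nA = i_nmda[which.max(abs(i_nmda))],
       peak_Ca_uM = max(ca))
}
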