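#' Gate kinetics tables
#'
#' Steady-state activation and time constant of every gating variable at the
#' given potentials. The Na (m, h) and delayed-rectifier K (n) gates use
#' Traub-Miles rate forms with a common voltage offset; the muscarinic K
#' gate is a Boltzmann with a bell-shaped time constant; the anomalous
#' (inward) rectifier gate is a hyperpolarization-activated Boltzmann with
#' fixed time constant.
#'
#' @param V Membrane potentials, mV.
#' @param kinetics Named kinetics vector as in [default_biophysics()].
#' @return Matrix with columns `<gate>_inf` and `<gate>_tau` (ms) for gates
#'   m, h, n, km, kir.
#' @export
gate_tables <- function(V, kinetics = default_biophysics()$kinetics) {
  cpp_gate_tables(as.numeric(V), kinetics)
}

#' Advance gating variables by first-order kinetics
#'
#' Each gate relaxes exponentially toward its voltage-dependent steady
#' state: x <- x_inf + (x - x_inf) exp(-dt / tau). Values remain in [0, 1]
#' for any voltage trajectory because x_inf does.
#'
#' @param gate_state Named numeric vector with entries m, h, n, km, kir in
#'   [0, 1].
#' @param V Membrane potential, mV.
#' @param dt Time step, ms.
#' @param kinetics Kinetics vector.
#' @return Updated gate vector.
#' @export
gate_step <- function(gate_state, V, dt, kinetics = default_biophysics()$kinetics) {
  stopifnot(dt > 0, all(gate_state >= 0 & gate_state <= 1))
  tab <- gate_tables(V, kinetics)[1, ]
  g <- gate_state
  for (nm in c("m", "h", "n", "km", "kir")) {
    inf <- tab[[paste0(nm, "_inf")]]
    tau <- tab[[paste0(nm, "_tau")]]
    g[[nm]] <- inf + (g[[nm]] - inf) * exp(-dt / tau)
  }
  g
}

#' Steady-state gate vector at a holding potential
#'
#' @param V Membrane potential, mV.
#' @param kinetics Kinetics vector.
#' @return Named gate vector (m, h, n, km, kir).
#' @export
gate_steady_state <- function(V, kinetics = default_biophysics()$kinetics) {
  tab <- gate_tables(V, kinetics)[1, ]
  c(m = tab[["m_inf"]], h = tab[["h_inf"]], n = tab[["n_inf"]],
    km = tab[["km_inf"]], kir = tab[["kir_inf"]])
}

#' Conductance-based channel current density
#'
#' I = density prod(gates^exponents) (E - V), the standard
#' Hodgkin-Huxley form. Exponents are m^3 h for Na, n^4 for the delayed
#' rectifier, and a single first-power gate for the muscarinic and
#' anomalous rectifier currents.
#'
#' @param channel One of `"na"`, `"kdr"`, `"km"`, `"kir"`.
#' @param gate_state Named gate vector (see [gate_steady_state()]).
#' @param V Membrane potential, mV.
#' @param density Channel density, S/m^2.
#' @param reversal Reversal potential, mV.
#' @return Current density, A/m^2 (positive = depolarizing).
#' @export
channel_current <- function(channel, gate_state, V, density, reversal) {
  channel <- match.arg(channel, c("na", "kdr", "km", "kir"))
  stopifnot(density >= 0, all(gate_state >= 0 & gate_state <= 1))
  open <- switch(channel,
    na = gate_state[["m"]]^3 * gate_state[["h"]],
    kdr = gate_state[["n"]]^4,
    km = gate_state[["km"]],
    kir = gate_state[["kir"]])
  density * open * (reversal - V) / 1000
}
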