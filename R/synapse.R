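#' Dual-exponential synaptic waveform utilities
#'
#' The AMPA and NMDA conductances follow a difference of exponentials with
#' rising constant tau1 and decaying constant tau2. The waveform is
#' peak-normalized: its maximum over time equals the channel's maximal
#' conductance (so the AMPA transient peaks at exactly 1 nS).
#'
#' @param tau1,tau2 Rising and decaying time constants, ms.
#' @return `dual_exp_peak_time` gives the time of the waveform maximum (ms);
#'   `dual_exp_shape` the normalized waveform (peak 1) at `t` ms.
#' @keywords internal
dual_exp_peak_time <- function(tau1, tau2) {
  tau1 * tau2 * log(tau2 / tau1) / (tau2 - tau1)
}

dual_exp_shape <- function(t, tau1, tau2) {
  tstar <- dual_exp_peak_time(tau1, tau2)
  norm <- exp(-tstar / tau2) - exp(-tstar / tau1)
  ifelse(t < 0, 0, (exp(-t / tau2) - exp(-t / tau1)) / norm)
}

#' AMPA receptor conductance
#'
#' Peak-normalized dual-exponential AMPA conductance for a single synaptic
#' activation. Zero before onset, peaks at `g_max` (1 nS by default) at
#' t* = tau1 tau2 ln(tau2/tau1)/(tau2 - tau1), and decays back to zero.
#'
#' @param t_since_onset Time since the activation, ms (vectorized).
#' @param params An [ampa_params()] list.
#' @return Conductance, nS.
#' @export
ampa_conductance <- function(t_since_onset, params = ampa_params()) {
  params$g_max * dual_exp_shape(t_since_onset, params$tau1, params$tau2)
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' The open fraction 1 / (1 + eta [Mg] exp(-gamma V)), with eta in mM^-1,
#' gamma in V^-1 and V the membrane potential. The factor lies in (0, 1],
#' increases monotonically with depolarization, and equals 1 in
#' magnesium-free solution.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param mg Extracellular magnesium, mM.
#' @param params An [nmda_params()] list (supplies eta and gamma).
#' @return Dimensionless open fraction.
#' @export
mg_block <- function(V, mg = NULL, params = nmda_params()) {
  if (is.null(mg)) mg <- params$mg
  1 / (1 + params$eta * mg * exp(-params$gamma * V / 1000))
}

#' NMDA receptor conductance
#'
#' Peak-normalized dual-exponential waveform multiplied by the magnesium
#' block. Strictly below `g_max` whenever magnesium is present, because the
#' block factor never reaches 1 at finite potentials.
#'
#' @param t_since_onset Time since the activation, ms.
#' @param V Membrane potential of the spine head, mV.
#' @param params An [nmda_params()] list.
#' @return Conductance, nS.
#' @export
nmda_conductance <- function(t_since_onset, V, params = nmda_params()) {
  params$g_max * dual_exp_shape(t_since_onset, params$tau1, params$tau2) *
    mg_block(V, params$mg, params)
}

#' Synaptic (ohmic) current
#'
#' I = G (E - Vm): positive (depolarizing, inward) while the membrane is
#' below the channel's reversal potential.
#'
#' @param G Conductance, nS.
#' @param E Reversal potential, mV.
#' @param Vm Membrane potential, mV.
#' @return Current, nA.
#' @export
synaptic_current <- function(G, E, Vm) {
  stopifnot(all(G >= 0))
  G * (E - Vm) / 1000
}

#' Calcium shell diffusion constant
#'
#' B = 5.2e-6 / (a L) with the shell area a and thickness L in SI base
#' units, divided by a dimensionless buffering factor. With a = 2 um^2,
#' L = 0.1 um and divisor 10, B = 2.6e12.
#'
#' @param area Shell area, um^2.
#' @param thickness Shell thickness, um.
#' @param buffering_divisor Buffering factor.
#' @return B, mol C^-1 m^-3.
#' @export
compute_shell_constant <- function(area = 2, thickness = 0.1,
                                   buffering_divisor = 10) {
  if (area <= 0 || thickness <= 0) stop("shell geometry must be positive")
  a_si <- area * 1e-12      # m^2
  l_si <- thickness * 1e-6  # m
  (5.2e-6 / (a_si * l_si)) / buffering_divisor
}

#' Advance the spine-head calcium shell
#'
#' Integrates d[Ca]/dt = B I_Ca - r ([Ca] - [Ca]_rest) over `dt` by exact
#' exponential relaxation (the equation is linear in [Ca] for a constant
#' current). With no current the concentration relaxes toward the resting
#' 0.05 uM at rate r; a constant inward current settles at
#' [Ca]_rest + B I_Ca / r.
#'
#' @param ca Current shell calcium, uM.
#' @param I_Ca Calcium current into the shell, nA (inward positive).
#' @param dt Time step, ms.
#' @param state A [ca_shell_params()] list.
#' @return Shell calcium after `dt`, uM (never negative).
#' @export
ca_shell_step <- function(ca, I_Ca, dt, state = ca_shell_params()) {
  stopifnot(all(ca >= 0), dt > 0)
  r <- state$extrusion_rate                 # s^-1
  # B [mol C^-1 m^-3] * I [A] = mol m^-3 s^-1 = mM/s = 1e3 uM/s
  influx <- state$B * (I_Ca * 1e-9) * 1e3   # uM/s
  ca_inf <- state$ca_rest + influx / r
  out <- ca_inf + (ca - ca_inf) * exp(-r * dt / 1000)
  pmax(out, 0)
}

#' Fractional calcium current through NMDA channels
#'
#' The fraction Pf of the NMDA current carried by calcium, from the
#' constant-field description of mixed divalent/monovalent permeation:
#' Pf = [Ca]o / ([Ca]o + (PCa/PM)^-1 ([M]/4) (1 - exp(2VF/RT))).
#' About 15% at the resting potential; the fraction is clipped to [0, 1]
#' above the reversal potential, where the constant-field expression leaves
#' its physical range.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param params A [ghk_params()] list.
#' @return Dimensionless fraction in [0, 1].
#' @export
fractional_ca <- function(V, params = ghk_params()) {
  v_si <- V / 1000
  expo <- exp(2 * v_si * params$faraday / (params$gas * params$temperature))
  denom <- params$ca_out +
    (1 / params$perm_ratio) * (params$monovalent / 4) * (1 - expo)
  pf <- ifelse(denom <= 0, 0, params$ca_out / denom)
  pmin(pmax(pf, 0), 1)
}

#' NMDA reversal potential from the extended GHK equation
#'
#' Vr = (RT/F) ln( sqrt(4[M]([M] + 4 (PCa/PM) [Ca]o)) / (2[M]) ). With the
#' default constants ([M] = 155 mM, PCa/PM = 3.6, [Ca]o = 2 mM, T =
#' 298.15 K) this evaluates to about 2.18 mV.
#'
#' @param params A [ghk_params()] list.
#' @return Reversal potential, mV.
#' @export
ghk_reversal <- function(params = ghk_params()) {
  m <- params$monovalent
  num <- sqrt(4 * m * (m + 4 * params$perm_ratio * params$ca_out))
  vr_si <- (params$gas * params$temperature / params$faraday) *
    log(num / (2 * m))
  vr_si * 1000
}

#' Calcium component of the NMDA current
#'
#' The inward calcium current feeding the spine-head shell:
#' I_Ca = Pf(V) I_NMDA, with Pf from [fractional_ca()].
#'
#' @param I_NMDA NMDA current, nA.
#' @param V Spine head membrane potential, mV.
#' @param params A [ghk_params()] list.
#' @return Calcium current, nA; magnitude never exceeds `I_NMDA`.
#' @export
ca_current_into_shell <- function(I_NMDA, V, params = ghk_params()) {
  fractional_ca(V, params) * I_NMDA
}
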