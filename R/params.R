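#' Structural parameters of the three granule cell classes
#'
#' Compartment and spine budgets of the stylized type I, II and III granule
#' cell morphologies. The compartment, spine and experimental (camera lucida)
#' spine counts are fixed quantities of the three reference cells; the
#' geometric defaults (segment lengths and diameters) are this package's own
#' stylization, chosen so that the branch topology and the per-region counts
#' are exact while metric geometry stays editable in one place.
#'
#' The compartment budget per class is allocated as: 1 soma + 15 trunk
#' compartments + deep-dendrite branches (4/3/2 branches of 5 compartments
#' for types I/II/III) + a terminal field organized in three depth zones with
#' 2 branches at the base, 3 in the middle and 4 at the tip.
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @return A list of structural constants for the class.
#' @export
cell_class_params <- function(cell_class) {
  cell_class <- match.arg(as.character(cell_class), c("I", "II", "III"))
  base <- list(
    cell_class = cell_class,
    soma_length = 12, soma_diameter = 12,        # um, sphere-equivalent cylinder
    trunk_n = 15, trunk_seg_length = 25,
    trunk_diameter = c(proximal = 2.0, distal = 2.0),
    trunk_proximal_n = 8,                        # segments 1..8 are "proximal trunk"
    deep_seg_n = 5, deep_seg_length = 30, deep_diameter = 0.7,
    terminal_seg_length = 25,
    terminal_diameter = c(base = 1.3, middle = 1.0, tip = 0.8),
    terminal_branches = c(base = 2, middle = 3, tip = 4),
    spine_neck_diameter = 0.23, spine_neck_length = 1.9,   # um
    spine_head_diameter = 0.8, spine_head_length = 0.8,    # um
    area_per_missing_spine = 3.37                          # um^2
  )
  cls <- switch(cell_class,
    I = list(
      n_compartments = 112L, n_spines = 112L, n_experimental_spines = 194L,
      n_deep_branches = 4L,
      terminal_zone_n = c(base = 8L, middle = 8L, tip = 9L),
      spine_exclusions = character(0)
    ),
    II = list(
      n_compartments = 114L, n_spines = 114L, n_experimental_spines = 118L,
      n_deep_branches = 3L,
      deep_seg_length = 40,        # type II deep dendrites reach deeper
      terminal_zone_n = c(base = 10L, middle = 9L, tip = 9L),
      spine_exclusions = character(0)
    ),
    III = list(
      n_compartments = 89L, n_spines = 61L, n_experimental_spines = 114L,
      n_deep_branches = 2L,
      terminal_zone_n = c(base = 8L, middle = 9L, tip = 5L),
      spine_exclusions = c("soma", "proximal_trunk", "deep")
    )
  )
  utils::modifyList(base, cls)
}

#' Default biophysical parameters
#'
#' Passive membrane, channel densities, channel kinetics constants, synaptic
#' receptor parameters, calcium shell constants and GHK constants for a
#' granule cell model. Densities are the package's factory calibration,
#' derived with [calibrate_cell()] against the reference electrophysiological
#' anchors: resting potential -65 mV, somatic chord input resistance 150
#' Mohm (a -0.1 nA step settles at -80 mV), and a rheobase of 0.04 nA for
#' types I/II and 0.03 nA for type III on a 1-s somatic step.
#'
#' Units follow the field's conventions: densities S/m^2, specific
#' capacitance F/m^2, axial resistivity ohm m, potentials mV, conductances
#' nS, times ms unless stated.
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @return Nested list of biophysical parameters.
#' @export
default_biophysics <- function(cell_class = "I") {
  cell_class <- match.arg(as.character(cell_class), c("I", "II", "III"))
  cal <- .factory_calibration[[cell_class]]
  list(
    cell_class = cell_class,
    v_rest = -65,                      # mV
    passive = list(
      cm = 0.01,                       # F/m^2 (1 uF/cm^2)
      ra = 1.0,                        # ohm m (100 ohm cm)
      g_pas = cal$g_pas,               # S/m^2, calibrated leak density
      e_pas = NA_real_                 # mV; solved at assembly so -65 mV is a fixed point
    ),
    # Channel densities in S/m^2 by region (terminal field split by depth
    # zone). Deep dendrites and spines are passive. The middle/base terminal
    # zones carry the sodium that makes the terminal field the spike
    # initiation gate; the thin tip branches are only weakly excitable so a
    # single spine's large local EPSP does not ignite its own branch.
    densities = cal$densities,
    reversals = c(na = 55, k = -90),   # mV
    # Kinetics table: Traub-Miles rate forms for Na and delayed-rectifier K
    # with a common voltage offset vt (mV); Boltzmann inward (anomalous)
    # rectifier; Yamada-style non-inactivating muscarinic K.
    kinetics = c(
      vt_na = cal$vt_na, vt_k = cal$vt_k,
      km_vhalf = -35, km_slope = 10, km_taumax = 303,
      kir_vhalf = -75, kir_slope = 8, kir_tau = 100
    ),
    synapse = list(
      ampa = ampa_params(),
      nmda = nmda_params(),
      ghk = ghk_params(),
      shell = ca_shell_params()
    )
  )
}

# Factory calibration of the free parameters (see calibrate_cell(); the
# anchors and the derivation are documented in the methods vignette).
.factory_densities <- function(na_soma = 265, na_trunk = 222, kdr_soma = 900) {
  list(
    soma            = c(na = na_soma, kdr = kdr_soma, km = 3, kir = 5),
    trunk_proximal  = c(na = na_trunk, kdr = 700, km = 1, kir = 5),
    trunk_distal    = c(na = na_trunk, kdr = 700, km = 1, kir = 5),
    terminal_base   = c(na = 250, kdr = 500, km = 0, kir = 0),
    terminal_middle = c(na = 250, kdr = 500, km = 0, kir = 0),
    terminal_tip    = c(na = 50, kdr = 300, km = 0, kir = 0),
    deep            = c(na = 0, kdr = 0, km = 0, kir = 0)
  )
}

.factory_calibration <- list(
  I = list(g_pas = 1.3605, vt_na = -67, vt_k = -67,
           densities = .factory_densities(265, 222)),
  II = list(g_pas = 1.3994, vt_na = -67, vt_k = -67,
            densities = .factory_densities(275.6, 230.88)),
  III = list(g_pas = 1.7137, vt_na = -67, vt_k = -67,
             densities = .factory_densities(344.5, 288.6))
)

#' AMPA receptor parameters
#'
#' Dual-exponential AMPA conductance with rise 2 ms, decay 5.5 ms, maximal
#' conductance 1 nS and reversal potential 0 mV. The waveform is
#' peak-normalized so its maximum equals `g_max`.
#'
#' @param g_max Maximal conductance, nS.
#' @param tau1,tau2 Rising and decaying time constants, ms.
#' @param reversal Reversal potential, mV.
#' @export
ampa_params <- function(g_max = 1.0, tau1 = 2.0, tau2 = 5.5, reversal = 0.0) {
  stopifnot(g_max > 0, tau1 > 0, tau2 > 0, tau1 != tau2)
  list(g_max = g_max, tau1 = tau1, tau2 = tau2, reversal = reversal)
}

#' NMDA receptor parameters
#'
#' Dual-exponential NMDA conductance (rise 52 ms, decay 343 ms, maximal
#' conductance 0.593 nS) gated by the voltage-dependent magnesium block
#' 1 / (1 + eta [Mg] exp(-gamma V)), with eta in mM^-1 and gamma in V^-1.
#' The reversal potential defaults to the extended-GHK value
#' ([ghk_reversal()], about 2.18 mV).
#'
#' @param g_max Maximal conductance, nS.
#' @param tau1,tau2 Rising and decaying time constants, ms.
#' @param eta Magnesium sensitivity, mM^-1.
#' @param gamma Voltage sensitivity of the block, V^-1.
#' @param mg Extracellular magnesium concentration, mM.
#' @param reversal Reversal potential, mV.
#' @export
nmda_params <- function(g_max = 0.593, tau1 = 52, tau2 = 343,
                        eta = 0.2801, gamma = 62, mg = 1.2,
                        reversal = ghk_reversal(ghk_params())) {
  stopifnot(g_max > 0, tau1 > 0, tau2 > 0, tau1 != tau2,
            eta > 0, gamma > 0, mg >= 0)
  list(g_max = g_max, tau1 = tau1, tau2 = tau2, eta = eta, gamma = gamma,
       mg = mg, reversal = reversal)
}

#' Extended Goldman-Hodgkin-Katz constants
#'
#' Constants of the mixed monovalent/divalent GHK description of the NMDA
#' channel: extracellular calcium, total monovalent concentration, the
#' Ca/monovalent permeability ratio, temperature and the physical constants.
#'
#' @param ca_out Extracellular free calcium, mM.
#' @param monovalent Monovalent ion concentration, mM.
#' @param perm_ratio Permeability ratio PCa/PM (dimensionless).
#' @param temperature Temperature, K.
#' @param faraday Faraday constant, C/mol.
#' @param gas Gas constant, J/(K mol).
#' @export
ghk_params <- function(ca_out = 2, monovalent = 155, perm_ratio = 3.6,
                       temperature = 298.15, faraday = 96485, gas = 8.314) {
  stopifnot(ca_out > 0, monovalent > 0, perm_ratio > 0, temperature > 0)
  list(ca_out = ca_out, monovalent = monovalent, perm_ratio = perm_ratio,
       temperature = temperature, faraday = faraday, gas = gas)
}

#' Calcium shell parameters
#'
#' Thin sub-membrane shell in the spine head. The diffusion constant is
#' B = 5.2e-6 / (a L) in SI units, divided by a buffering factor; with the
#' default head area a = 2 um^2, thickness L = 0.1 um and divisor 10 this
#' gives B = 2.6e12 (mol C^-1 m^-3). Calcium is extruded at rate r toward
#' the resting concentration.
#'
#' @param area Shell (spine head) membrane area, um^2.
#' @param thickness Shell thickness, um.
#' @param buffering_divisor Dimensionless buffering factor applied to B.
#' @param extrusion_rate Extrusion rate r, s^-1.
#' @param ca_rest Resting calcium concentration, uM.
#' @export
ca_shell_params <- function(area = 2, thickness = 0.1, buffering_divisor = 10,
                            extrusion_rate = 870, ca_rest = 0.05) {
  stopifnot(area > 0, thickness > 0, buffering_divisor > 0, extrusion_rate > 0)
  list(area = area, thickness = thickness,
       buffering_divisor = buffering_divisor,
       extrusion_rate = extrusion_rate, ca_rest = ca_rest,
       B = compute_shell_constant(area, thickness, buffering_divisor))
}

#' Electrophysiological calibration anchors
#'
#' The reference anchors that pin down the free density parameters: resting
#' potential -65 mV, rheobase 0.04 nA (types I and II) or 0.03 nA (type
#' III) on a 1-s somatic step, and the somatic chord input resistance of
#' 150 Mohm defined by a -0.1 nA step settling at -80 mV.
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @export
calibration_targets <- function(cell_class = "I") {
  cell_class <- match.arg(as.character(cell_class), c("I", "II", "III"))
  list(
    v_rest = -65,                                   # mV
    rheobase = if (cell_class == "III") 0.03 else 0.04,  # nA
    input_resistance = 150,                         # Mohm (chord, -0.1 nA -> -80 mV)
    hyperpol_hold = list(current = -0.1, v_target = -80)
  )
}
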