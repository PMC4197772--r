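---
title: "Compartmental models of olfactory bulb granule cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental models of olfactory bulb granule cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(granulesim)
```

Granule cells are the axonless inhibitory interneurons of the olfactory
bulb. Their distal (terminal) dendrites carry reciprocal dendrodendritic
synapses with mitral/tufted cell lateral dendrites: glutamate released onto
a granule-cell spine opens AMPA and NMDA receptors, calcium entering
through the NMDA channel triggers GABA release back onto the principal
cell. How many co-active spines it takes to make a granule cell fire — and
where in the cell the spike starts — therefore controls recurrent and
lateral inhibition in the bulb. This package builds multicompartment models
of the three morphological granule-cell classes (types I, II, III), with
active dendrites and explicit two-compartment spines, and drives them
through the stimulation protocols that probe exactly those questions.

## The model

### Morphology

Each cell is a rooted tree of cylindrical compartments: a soma, an
ascending trunk (15 segments), short deep-dendrite branches off the
proximal trunk, and a terminal field that branches with depth — 2 branches
in its base zone, 3 in the middle, 4 at the tip. The per-class compartment
and spine budgets are fixed constants of the three reference cells:

| class | compartments | spines | reconstructed spines | deep branches |
|-------|-------------:|-------:|---------------------:|--------------:|
| I     | 112          | 112    | 194                  | 4             |
| II    | 114          | 114    | 118                  | 3             |
| III   | 89           | 61     | 114                  | 2             |

The reconstructions on which these counts are based are not distributed
with their metric geometry, so segment lengths and diameters here are a
stylization, kept in one editable table (`cell_class_params()`): soma
12 µm, trunk 375 µm at 2.0 µm diameter, deep branches 150 µm (200 µm in
type II) at 0.7 µm, terminal zones 200/200/225 µm at 1.3/1.0/0.8 µm. The
topology and counts, not the metric details, carry the scientific claims;
the geometry was chosen once so that the calibrated cells reproduce the
anchor electrophysiology below and was not revisited afterwards.

Spines are a 0.23 × 1.9 µm neck plus a 0.8 × 0.8 µm head, one per eligible
compartment. Types I and II carry a spine on every compartment including
the soma — granule-cell somata do bear spines (gemmules), and this is the
only reading under which "one spine per compartment" and the stated equal
compartment/spine counts are simultaneously satisfiable. Type III excludes
the soma, proximal trunk and deep dendrites and fills from the distal
trunk and terminal tip downward. The membrane area of reconstructed spines
that are not explicitly modeled is added back uniformly over the
spine-bearing compartments at 3.37 µm² per missing spine.

### Synapses and spine calcium

Both receptor conductances are peak-normalized differences of
exponentials; the waveform maximum equals the channel maximum:

* AMPA: rise 2 ms, decay 5.5 ms, g_max 1 nS, reversal 0 mV.
* NMDA: rise 52 ms, decay 343 ms, g_max 0.593 nS, multiplied by the
  magnesium block 1/(1 + η[Mg²⁺]e^(−γV)) with η = 0.2801 mM⁻¹,
  γ = 62 V⁻¹, [Mg²⁺] = 1.2 mM by default.

η and γ carry no stated units; mM⁻¹ and V⁻¹ are adopted because they
reproduce a sensible open fraction (≈ 0.05 at −65 mV). The NMDA reversal
potential comes from the extended Goldman–Hodgkin–Katz expression for
mixed monovalent/divalent permeation ([M] = 155 mM, PCa/PM = 3.6,
[Ca²⁺]ₒ = 2 mM, T = 298.15 K), giving Vr ≈ 2.19 mV. The fraction of the
NMDA current carried by calcium is the constant-field expression
`fractional_ca()`, ≈ 15.8 % at rest; strictly evaluated it *increases*
toward the reversal potential (the often-assumed monotone decrease is
wrong for this formula — the monovalent driving force collapses faster
than the divalent one). Above the reversal potential the expression leaves
its physical range and is clipped to [0, 1].

Each synaptically active spine head carries a thin calcium shell:
d[Ca²⁺]/dt = B·I_Ca − r·([Ca²⁺] − 0.05 µM), with B = 5.2·10⁻⁶/(aL)
divided by a buffering factor of 10 (a = 2 µm², L = 0.1 µm, so
B = 2.6·10¹²), r = 870 s⁻¹, and I_Ca = Pf(V)·I_NMDA. As literally written
(decay proportional to [Ca²⁺]) the shell would relax to zero,
contradicting the stated 0.05 µM resting concentration; the extrusion
term here pulls toward that resting value.

### Active membrane

Channel kinetics for the four currents (rat-brain Na, delayed-rectifier
K, anomalous/inward-rectifier K, non-inactivating muscarinic K) are not
available from the source of the original reconstructions, so the package
implements standard published forms — Traub–Miles rate functions for Na
(m³h) and K_dr (n⁴) with a common voltage offset of −67 mV, a Boltzmann
inward rectifier (V½ −75 mV, slope 8 mV, τ 100 ms), and a Yamada-style
M-current — and treats densities as free parameters pinned by reference
electrophysiology:

* resting potential −65 mV (enforced exactly by solving the leak reversal
  per compartment so the quiescent cell is a fixed point);
* a −0.1 nA somatic step settles at −80 mV, i.e. a 150 MΩ chord input
  resistance (leak density bisection, per class);
* rheobase on a 1-s somatic step: 0.04 nA for types I and II, 0.03 nA for
  type III, at 0.005 nA resolution (Na-density bisection). The reference threshold
  statement is ambiguous between types II and III for the 0.03 nA value;
  this package assigns it to type III.

Deep dendrites and spines are passive. The terminal field carries the
sodium that makes it the spike-initiation gate, graded by zone: the
middle/base zones are the igniters (250 S/m²) while the thin tip branches
are only weakly excitable (50 S/m²) — a single spine's large local EPSP
(~20 mV on a 0.8 µm branch) must not ignite its own branch, whereas two
spines on sibling tips summing at their shared middle branch must. The
slow inward rectifier on the soma/trunk gives slow (DC) inputs extra gain
relative to brief EPSPs, which is what lets a 6 mV steady depolarization
(0.04 nA × 150 MΩ) reach threshold while an 8–9 mV transient EPSP from
two trunk spines does not. Factory densities per class are stored in
`default_biophysics()`; `calibrate_cell()` re-derives them from the
anchors.

### Numerics

Voltages are advanced by the Crank–Nicolson semi-implicit scheme with
staggered gate updates; the implicit solve is one O(N) Hines sweep over
the tree (leaf-to-root elimination, root-to-leaf back-substitution),
implemented in C++. Gates and shell calcium advance by exact exponential
relaxation over the step; synaptic waveforms are evaluated in closed form
at the step midpoint; the magnesium block uses the current voltage.
Voltage clamps are exact row replacements in the linear system, so
clamped sites hold their level to machine precision without a clamp-gain
parameter. The default step is 10 µs with 0.1 ms trace sampling;
convergence is verified against the closed-form RC response
(second-order in dt) and a dense-matrix solve on random small trees
(relative error < 10⁻⁹ per step). The pipeline contains no random number
generation: every run is bit-reproducible, and the `seed` field of the
run configuration is reserved but unused.

## Experiments

The drivers in `R/experiments.R` encode the study protocols: spike
detection (upward 0 mV crossing, 2 ms refractory separation, linear
interpolation between samples; the criterion itself is a package choice,
since none is stated for the protocols), the minimum-spine-count search per dendritic
region, initiation-site comparison between the distal trunk ("terminal
region of the trunk") and the soma, tangential-plane stimulation of the
type I terminal field (4 spines at the tip plane, 3 at the middle, 2 at
the base, emulating a mitral/tufted secondary dendrite crossing the
radially-oriented granule dendrites), optionally under a −0.1 nA somatic
hold, and magnesium sweeps. Trials run 500 ms with synapse onset at
50 ms (200 ms under the hold, to let it settle); all selected spines are
activated simultaneously.

With the factory calibration the models reproduce:

* minimum activated spines for a somatic spike: 2 at the terminal tips,
  3 on the trunk, 4 on the deep dendrites (type I); type II fails to fire
  from its 3 deep branches; type III fires from 3 distal-trunk spines like
  the other classes;
* first-spike latency strictly decreasing with the number of spines;
* subthreshold somatic EPSPs growing with the number of spines;
* NMDA conductance and somatic EPSP decreasing monotonically with
  magnesium, with the unblocked peak reaching the 0.593 nS maximum;
* dendritic (distal-trunk before soma) spike initiation for every
  terminal-field stimulation in all three classes.

## Known limitations

Two reference observations are *not* reproduced, and the corresponding
acceptance tests are deliberately left failing rather than weakened:

* **Initiation site for proximal stimuli.** For proximal-trunk and
  deep-dendrite stimulation of types I/II, the somatic 0 mV crossing leads
  the distal-trunk crossing by 0.2–0.5 ms: the proximal drive ignites the
  soma/proximal trunk first and the spike backpropagates outward. A wide
  design exploration (tapered trunks, distal sodium gradients, slow-Kir DC
  boosts, large low-density somata, axial resistivity 0.6–2.0 Ω·m) found
  no parameterization that yields dendrite-first initiation for proximal
  inputs while simultaneously holding the calibration anchors and the
  spine-count thresholds; in the stylized morphology those constraints
  are incompatible, and the dendrite-first order for proximal stimuli
  apparently depends on reconstruction-specific geometry that is not
  available.
* **Tip plane under the hyperpolarizing hold.** The −0.1 nA somatic hold
  shifts the soma to −80 mV but reaches the terminal field attenuated to
  ~3 mV, which suppresses spikes from the middle (3-spine) plane but not
  from the tip (4-spine) plane: the window between "two tip spines at rest
  must fire" and "four tip spines under the hold must not" closes to
  ~1 mV and the model sits on the wrong side of it. Middle- and base-plane
  behavior under the hold (no spikes, dendritic EPSP exceeding the
  somatic one, middle amplitude above base) is reproduced.

The synthetic morphologies are stylizations: they reproduce compartment
and spine counts, branch topology, spine-distribution differences between
classes and the calibrated electrophysiology, but not camera-lucida
geometry, tortuosity, diameter tapers within zones, or the real cells'
morphological variability (a single representative per class). Passing
tests therefore speak to the qualitative
integration regime — regional spine-count thresholds, cooperative
dendritic ignition, magnesium dependence — not to quantitative
predictions for any real reconstructed cell. Receptor desensitization,
release stochasticity, TRP channels and the downstream GABA release are
outside the model.

## Reproducing the numbers

```{r, eval = FALSE}
model <- granule_model("I")
min_spines_for_spike(model, "terminal_tip")
ap_origin(model, "terminal_tip")
tangential_stimulation(model, "tip", hold_current_nA = -0.1)
mg_sweep(model)
fi_curve(model, c(0, 0.02, 0.04, 0.05, 0.1))
```

`scripts/acceptance.R` recomputes the headline quantities (GHK reversal,
resting calcium fraction, AMPA/NMDA conductance peaks, construction
counts, the −80 mV hold) from a fresh build of the models. The test suite
runs the same protocols at the production 10 µs step with scaled trial
counts chosen to keep a full run in a few minutes.
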