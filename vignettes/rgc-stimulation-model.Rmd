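---
title: "Modeling retinal ganglion cell responses to epiretinal pulse trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling retinal ganglion cell responses to epiretinal pulse trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epiretinal prostheses drive retinal ganglion cells (RGCs) with charge-balanced
biphasic current pulses from disk electrodes sitting on the inner retinal
surface. RGC subtypes differ in morphology and membrane composition, and those
differences translate into different abilities to follow high-rate pulse
trains. `rgcstim` models two contrasting subtypes — a large monostratified
cell ("A2-like": 20 µm soma, 320 µm dendritic field, calcium-rich membrane,
no h-current) and a small bistratified cell ("D1-like": 12 µm soma, 144 µm
field, calcium-poor, h-current present) — and provides the protocol suite
needed to ask when stimulus parameters (amplitude, pulse width, interphase
gap, frequency) activate one subtype selectively.

## Membrane model

Each compartment carries seven voltage-gated conductances plus leak:

* transient Na (`g_Na`, gates m³h), delayed-rectifier K (`g_K`, n⁴),
  A-type K (`g_KA`, a³h_A), Ca-activated K (`g_KCa`, gateless),
  high-threshold Ca (`g_Ca`, c³), HCN/h (`g_h`, q), and a low-threshold
  T-type Ca (`g_T`, t_m²t_h).
* Na, K, A-type and high-threshold Ca gates use the classical
  Fohlmeister–Miller amphibian-RGC rate equations; every coefficient is in
  `inst/extdata/gating_kinetics.csv` (one record per gate and role), which is
  the single source of truth for both the R reference implementation
  (`rate_functions()`) and the compiled solver.
* The h gate is a standard slow HCN model: half-activation −80 mV, slope
  8 mV, τ between 100 ms and 1 s (Gaussian in voltage). Its main effects at
  these time scales are a depolarized resting potential, a depolarizing sag
  under hyperpolarizing steps, and a shortened refractory period.
* The T-type model activates steeply at −45 mV with a sub-millisecond time
  constant and inactivates slowly (τ ≈ 30–110 ms). Two properties of this
  choice matter and are deliberate: a lower activation midpoint turns the
  calcium-rich soma into a spontaneous pacemaker (the resting state must be
  quiescent), and a slow activation gate would summate across the 5 ms
  inter-pulse intervals of 200 Hz trains, which is not how a fast
  low-threshold current behaves.
* Ca-carried currents reverse at the Nernst potential computed from the
  instantaneous intracellular concentration (Ca_o = 1.8 mM, divalent slope
  at 22 °C). No Q10 scaling is applied (kinetics are used at their reference
  temperature).

Channel densities for the two presets are shipped as structured text
(`inst/extdata/conductances_soma_dendrite.csv` and `conductances_axon.csv`)
mirroring the published tables, including the derived rows
`g_KA = 3 g_K` and `g_KCa = 0.004 g_K`. The axon table is not split by cell
type; it is applied identically to both presets, and channels it does not
list are absent from the axon. Passive parameters default to
C_m = 1 µF/cm², R_a = 110 Ω·cm, g_leak = 5×10⁻⁵ S/cm² at −65 mV.

## The calcium pool and the K_Ca operating point

Each Ca-bearing compartment has a single well-mixed submembrane shell:

dCa/dt = −I_Ca/(2 F d) − (Ca − Ca_rest)/τ_Ca

with shipped defaults d = 0.05 µm, τ_Ca = 5 ms, Ca_rest = 10⁻⁴ mM, and the
K_Ca activation factor (Ca/K_half)² / (1 + (Ca/K_half)²) with
K_half = 0.1 mM. These three constants are a joint calibration, and the
package treats them as such rather than as independent literature values:

* During pulse-train firing the A2-like soma accumulates submembrane calcium
  of order 0.1 mM per spike burst; the D1-like soma roughly a tenth of that
  (its `g_Ca` is 0.013 vs 0.137 S/cm²).
* `K_half` is placed on that operating range. If it is orders of magnitude
  below it, the Hill factor saturates for *both* cells and — because the
  D1 preset has the larger `g_K` and therefore the larger
  `g_KCa = 0.004 g_K` — a saturated coupling penalizes the calcium-*poor*
  cell more, which is backwards.
* τ_Ca = 5 ms makes the K_Ca conductance felt at the *next* pulse of a
  200 Hz train (5 ms later) much more than at the next pulse of a 120 Hz
  train (8.3 ms later): the residual calcium ratio between those two delays
  is ≈ 2.5. This is the mechanism by which a current tuned to 100% spike
  probability at 120 Hz can fail every other pulse at 200 Hz in the
  calcium-rich cell while the calcium-poor cell follows.

All three constants are arguments of `membrane_params()` and can be restored
to classical single-spike values (depth 0.1 µm, τ 1.5 ms, K_half 10⁻³ mM) by
users interested in isolated-spike behavior rather than train-following.

## Extracellular field and stimulus

The stimulating electrode is a 200 µm-diameter equipotential disk on the
surface of a semi-infinite homogeneous medium (default σ = 0.1 S/m), with a
monopolar return at infinity:

V(r, z) = I/(4σa) · (2/π) · asin( 2a / (√((r−a)²+z²) + √((r+a)²+z²)) )

This closed form equals I/(4σa) on the disk and decays to the half-space
point source I/(2πσR) far away. It stands in for a full voxel conductor
model of the layered retina; consequently *absolute* threshold currents are
calibration-dependent and about an order of magnitude below the device
range, while relative effects (pulse width, gap, frequency, soma size) are
the quantities of interest. Compartments couple to the field
quasi-statically: each gets a unit-current coefficient φ (mV/µA) from its
center position, and the extracellular potential enters the cable equation
through the intracellular potential V_i = V_m + V_e (axial currents are
driven by V_i differences).

Stimuli are symmetric charge-balanced biphasic trains, cathodic phase first,
optional interphase gap, sampled piecewise-constant at step midpoints with
the time step refined to divide the phase durations exactly — this makes the
sampled waveform charge-balanced period by period to floating-point
accuracy.

## Solver

The cable equation is integrated by a staggered scheme written in C++:
gates advance by exact exponential relaxation at the current voltage, then
the voltage-linear system (membrane conductances frozen over the step, the
tree solved exactly by Hines elimination) advances by backward Euler
(default) or Crank–Nicolson. dt defaults to 0.01 ms uniformly across
protocols, so that tuned-current comparisons across pulse widths share one
discretization. Compartments are ≤ 10 µm long on the soma and proximal axon
bands and ≤ 25 µm on dendrites and distal axon, which resolves the field
gradient near the electrode. Divergence (|V| > 500 mV) aborts a run with
the failure time; it occurs only for stimuli several-fold above the
model's threshold range.

Spikes are upward crossings of −20 mV with a 1.5 ms detector dead time. The
threshold sits well above the small abortive somatic events that appear
when the axon initiation site fires but fails to invade a refractory soma —
those events must *not* be counted, and their presence at amplitudes inside
a response plateau is itself part of the modeled phenomenology. Spike
probability is counted spikes (at most one per stimulus period) over
delivered pulses; firing rate is probability × frequency.

## The reduced cell pair

`make_reduced_pair()` builds the controlled comparison used throughout the
protocol suite: two small cells that differ **only** in soma diameter
(20 vs 12 µm), equivalent-dendrite length (the cells' dendritic-field radii,
160 vs 72 µm), and the preset densities; passive parameters, axon geometry
(four bands: hillock, sodium-channel band, narrow segment, distal axon, with
the high Na densities of the shared axon table), electrode placement (soma
on-axis at 50 µm standoff) and solver settings are identical. The
single-compartment variant (`budget = 1`) carries the exact soma densities
and is used for intracellular experiments (channel swaps, sag); a spatially
uniform extracellular potential cannot excite an isopotential compartment,
so extracellular protocols use the axon-bearing variant. The equivalent
dendrite matters: it carries the A2 cell's dendritic calcium load and the
D1 cell's dendritic T/h currents, which are part of the intrinsic contrast
between the types.

The stylized full morphologies (`generate_stylized_morphology()`) are
geometric stand-ins — radial tapering dendrites descending to one or two
stratification planes — that satisfy the gross published geometry (soma and
field diameters, mono/bistratification). They do not reproduce real arbor
topology (no branching statistics, no Sholl profile), so passing tests on
them validate the pipeline, not anatomical realism.

## Protocols and their conventions

* **Threshold**: minimum amplitude on a fixed grid achieving 100% spike
  probability at 120 Hz, by doubling bracket plus bisection, with a
  minimality certificate (the next lower grid amplitude fails).
  `find_threshold()` defaults to a 1 µA grid; the sweep protocols
  (`strength_duration_sweep()`, `ipg_sweep()`) default to the 5 µA grid of
  the published amplitude scans. The difference is not cosmetic: at
  razor-exact tuning both cells sit on the 200 Hz alternation knife edge,
  while the protocol grid leaves each cell the same one-grid-step margin.
* **Frequency response**: the tuned current (per cell, per pulse width or
  gap) is then applied at 200 Hz; the rate difference is signed D1 − A2.
* **Rate-vs-amplitude** curves use the train duration (default 1 s; the
  shipped tests and acceptance script use 500 ms, i.e. 60 tuning periods at
  120 Hz and 100 test pulses at 200 Hz, which resolves probabilities to
  1–2%). The **saturation window** is the widest contiguous amplitude run
  with probability within ±0.02 of 0.5.
* **Refractory period**: paired identical extracellular biphasic pulses at
  1.5× single-pulse threshold; bisection (0.5 ms grid) for the smallest
  interval at which the second pulse still elicits a spike.
* **Sag**: a sustained hyperpolarizing somatic step, auto-scaled to the
  cell's input resistance (target ≈ 25 mV early hyperpolarization) so that
  cells of different size operate the h-current over comparable voltage
  ranges; sag = V(end of step) − V(minimum).

## What the reduced model does and does not reproduce

With the shipped calibration the reduced pair reproduces, directionally: the
decaying and flattening strength–duration curve; threshold relief by an
interphase gap; the larger D1−A2 rate difference at 200 Hz for short pulses
(+100 Hz at PW 0.1 ms vs 0 at 1 ms) and its collapse when a 1 ms gap is
added; the higher threshold of an enlarged soma; the left-shift of the
response curve when the A2 calcium density is lowered; the narrower spike
with lower calcium; and the shorter refractory period plus larger sag with
the h conductance.

It does **not** reproduce a *wide* 50%-probability saturation window whose
width is controlled by the calcium density: here the 50% plateau is the
alternation band at threshold, about 1 µA wide for both the calcium-rich
and calcium-lowered variants — that width is set by the shared axon's
recovery dynamics. A wide calcium-controlled window appears to require the
full-morphology, full-volume-conductor configuration. The corresponding
check is left failing rather than weakened, and the response-curve shift
(the excitability half of the same finding) is asserted instead.

Mode-locking at exactly-tuned currents is inherently knife-edged: it is
sensitive to the time step and to threshold resolution. The shipped
configuration (dt 0.01 ms, 5 µA protocol grid, 500 ms trains) is the study
condition; the package makes all of these explicit arguments rather than
hidden constants.

## Reproducing the numbers

```{r}
library(rgcstim)
pair <- make_reduced_pair()
th <- find_threshold(pair$a2, pulse_width = 0.1, frequency = 120,
                     resolution = 5, duration = 500)
tr <- pulse_train(th$current, 0.1, 0, 200, 500)
spike_probability(simulate_cell(pair$a2, tr)$spike_times, tr) * 200
```

`scripts/acceptance.R` re-derives every headline quantity (charges, field
anchors, thresholds, rate differentials, window widths, refractory periods,
sags, detector ground truth) from a fresh session and writes them to JSON;
see the README for the exact invocation.
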