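---
title: "Modeling magnetic stimulation of compartmental neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling magnetic stimulation of compartmental neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magstim)
```

## The model

A current pulse through a circular coil held above the tissue induces an
electric field that can polarize neuronal membranes. `magstim` couples
three classical components:

1. **The coil field.** The magnetic vector potential of a circular loop of
   radius $r$ carrying current $I$ is azimuthal, and in SI units

   $$A_\phi(\rho, z) = \frac{\mu}{4\pi}\,\frac{4 r}{\sqrt{(r+\rho)^2+z^2}}\;
     \frac{(2-m)K(m) - 2E(m)}{m},\qquad
     m = \frac{4 r \rho}{(r+\rho)^2+z^2},$$

   with $K$ and $E$ the complete elliptic integrals in the *parameter*
   convention ($m = k^2$, the convention of `pracma::ellipke`). Because the
   parameter/modulus mix-up is a classic silent bug, the test suite pins the
   convention against a Biot–Savart line-integral oracle
   ($A = \tfrac{\mu}{4\pi}\oint \mathrm{d}l/R$, resampled into up to $10^5$
   straight elements) to a relative error of $10^{-6}$. Arbitrary coil paths
   (e.g. a figure-of-eight) go through the same line integral.

   By Faraday's law the induced field of an $N$-turn coil is
   $E = -N\,\partial A/\partial t$, which separates into a spatial factor
   $S(x,y) = -N A_\phi(\rho, z_0)\hat\phi$ evaluated on the neuron plane at
   the coil standoff $z_0$, and a temporal factor $g(t) = \mathrm{d}I/\mathrm{d}t$.
   The engine evaluates $S$ analytically at compartment endpoints; sampled
   grids (`export_field_grid()`) exist only for export and visualization.

2. **The stimulator.** A series RLC discharge from a capacitor charged to
   $V_0$: underdamped when $R < 2\sqrt{L/C}$ (oscillatory,
   $I = \frac{V_0}{\omega L}e^{-\alpha t}\sin\omega t$,
   $\alpha = R/2L$, $\omega = \sqrt{1/LC - \alpha^2}$), overdamped otherwise
   (the boundary case is classified overdamped and evaluated by its
   critically damped closed form). Both branches satisfy $I(0)=0$ and
   $\mathrm{d}I/\mathrm{d}t(0) = V_0/L$ and are verified against an adaptive
   ODE integration of $L\dot I + RI + Q/C = 0$ to $10^{-6}$ relative. $V_0$
   is the search variable of the *magnetic threshold*: the smallest charge
   voltage that elicits an action potential.

3. **The neuron.** A branched tree of cylindrical sections (built-in
   geometry builders or SWC files), discretized into compartments and
   integrated as a cable with Hodgkin–Huxley, passive, or myelin membrane.

## How the induced field drives the cable

Only the field component parallel to each neurite matters (the
membrane-normal component is neglected, as is standard for thin fibers, and
the neuron is assumed planar, parallel to the coil). The induced axial field
$E_a$ interacts with the cytoplasmic resistance $r_a$ (per unit length) to
produce a transmembrane current per unit length $-\tfrac{1}{r_a}\,
\partial E_a/\partial a$. Two consequences anchor the implementation:

* the *activating function* $\lambda^2\,\partial E_a/\partial a$ predicts
  the steady-state polarization profile, with
  $\lambda = \sqrt{r_m/r_a} \propto \sqrt{d}$, so thicker compartments are
  preferentially polarized;
* a spatially uniform field along a straight uniform fiber produces no
  drive at all — only gradients (or geometry changes) stimulate.

Discretely, the engine evaluates $E_a = S \cdot \hat t$ at compartment
*boundary nodes* along each section's path and injects, into each
compartment, the current
$-(E_a^{\text{distal}} - E_a^{\text{proximal}})/r_a$ as a pure source with
zero reversal potential (independent of membrane voltage). The node tangent
$\hat t$ is the compartment chord at section ends and the normalized mean of
the two adjacent chords at interior nodes. This *node-tangent* form was a
deliberate choice over the naive per-segment difference (both endpoint
fields projected on the segment's own chord): the differences telescope
along the path, so straight-fiber results are identical, but a bend inside a
section correctly receives the localized drive
$E\cdot(\hat a_2 - \hat a_1)$ implied by the discontinuity of $E_a$ — with
the per-segment form a bent dendrite shows no threshold change at any angle,
which contradicts both the continuum limit and the reference phenomenology.
Differences are taken within sections only; branch points conserve axial
current and add no extra source, and sealed ends add no boundary term. A
corollary, documented as a limitation: a perfectly uniform field produces no
terminal "end effect" in this scheme.

## Membrane and solver

The `hh` mechanism is the classic squid parameter set at 6.3 °C
($\bar g_{Na} = 0.120$, $\bar g_K = 0.036$, $g_L = 0.0003$ S/cm²;
$E_{Na} = 50$, $E_K = -77$, $E_L = -54.3$ mV; $c_m = 1$ µF/cm²; axial
resistivity 35.4 Ω·cm; initialization at −65 mV), with the removable
singularities of the rate functions evaluated by their limits and an
optional voltage shift of the Na activation/inactivation curves
(`na_shift`) for excitability manipulations. Passive dendrites default to
$g_{pas} = 1/30000$ S/cm², $e_{pas} = -65$ mV (the reference experiments do
not print these values; both are configurable, and the morphology sweeps'
qualitative claims are insensitive to them). An unstimulated 50 ms
simulation drifts less than 0.1 mV from initialization.

**Myelin** is modeled as a purely capacitive sheath: zero conductance at the
ordinary specific capacitance of 1 µF/cm² — exactly what a compartment
carries when no mechanism is inserted into it. This was a genuinely open
design point (an idealized low-capacitance sheath, e.g. 0.04 µF/cm², is the
other common convention) and was settled mechanistically: with a
low-capacitance sheath the internodes integrate induced current over a very
long AC length constant, the nodes of Ranvier dominate initiation for soma
shifts beyond 0.3 cm, and the documented axonal-to-somatic initiation
transition at a 0.05 cm soma shift cannot occur; with the plain sheath the
transition follows the activating-function crossover between soma and fiber
and lands at 0.05 cm. Users wanting the low-capacitance idealization pass
`mechanism("myelin", cm = 0.04)`.

Space is discretized by the d-lambda rule: compartments no longer than 0.1
of the 100 Hz AC length constant (and never longer than an optional cap),
with an odd compartment count per section so that a mid-section bend falls
in a compartment interior, as in standard compartmental practice. The 16 cm
reference axon resolves to 339 compartments; halving the rule changes the
magnetic threshold by well under 1 % (tested). Time integration is implicit
backward Euler at 1 µs with gating variables advanced by the exponential
(`cnexp`) update at the pre-step voltage, and the branched linear system is
solved exactly per step by a Hines-ordered tree elimination (verified
against a dense LU reference to $10^{-10}$). Halving the time step changes
subthreshold peaks by <0.01 mV. The induced drive uses
$\mathrm{d}I/\mathrm{d}t$ evaluated analytically at each step midpoint; no
lookup tables or interpolation are involved anywhere.

## Protocols

Spike detection is an upward crossing of 0 mV (configurable) with a 1 ms
refractory separation, counted only in excitable compartments — passive or
myelinated compartments can be polarized across any criterion directly by
the induced drive without a regenerative event. Initiation sites take the
earliest crossing, ties broken by the largest dV/dt. Threshold searches
bisect $V_0$ (or the somatic square-pulse amplitude) after verifying, and if
needed expanding, the bracket; the reported value is the final bracket
midpoint, and equivalence with an exhaustive scan is tested. The sweep
drivers (`run_experiment()`) reproduce the standard experiment families:
threshold versus fiber diameter, coil position, bend/bifurcation/step
geometry, dendrite count (with current threshold and input resistance),
stimulator capacitance (strength–duration and device energy), soma shift of
a myelinated cell (initiation-site transition), and neuronal state (EPSP or
a preceding action potential before the pulse).

Artificial soma-bearing cells are placed with the soma at the
activating-function hotspot of the standard one-radius-shifted coil
(1.66 cm along the fiber line from the coil center): the reference
placement "at the field maximum" is exactly symmetric there, the along-cell
gradient vanishes, and a soma-bearing cell would receive no first-order
drive at all; the hotspot is the nearest well-posed realization and
preserves every claimed qualitative relation.

## Scales, units, and the voltage calibration

All field math is SI (m, s, V/m); morphologies are micrometers; the solver
works in the conventional mV/ms/nA/µS/nF system, with a single explicit
conversion layer between them. Config files accept unit-suffixed strings
("2cm", "13uH") to keep the mixed conventions honest.

One quantitative caveat deserves emphasis. With the correct SI field —
pinned by the line-integral oracle, and consistent with the fact that real
magnetic stimulators charge their capacitors to kilovolts — the magnetic
threshold of the 100 µm × 16 cm reference axon computes to ≈13.7 kV, not
the ≈36 V sometimes quoted for this configuration; the ratio is within 1 %
of $4\pi N$ ($N = 30$ turns), the factor produced by using $\mu$ in place of
$\mu/4\pi$ in the vector potential and applying the turn count twice. All
*location and shape* results (hotspot position, initiation sites and their
transitions, inverse-power diameter laws, monotonicities, correlations,
threshold ratios) are invariant under a global field scale and are
reproduced; absolute voltages from this package are on the physical scale.
No calibration factor is exposed or applied.

## What the geometry builders do and do not emulate

The builders generate idealized planar cells: uniform cylinders, a
length-equals-diameter soma (area-equivalent to the sphere), single-point
bends, symmetric Rall bifurcations, alternating internode/node axons.
Passing tests on these geometries demonstrates the numerical scheme and its
qualitative predictions; it does not establish quantitative thresholds for
real cortical neurons, which have tapering, 3-D arbors (the planar
assumption drops the field's z-decay across a real arbor), nonuniform
channel densities, and dendritic nonlinearities that are out of scope here.
Two findings from the generic cells differ quantitatively from their
realistic-morphology analogues and are reported as computed: the free-offset
power-law exponent of threshold versus diameter is −1 for a uniform
unmyelinated axon (the activating function scales as
$\lambda^2 \propto d$; the often-quoted −2 belongs to myelinated fibers,
whose internode spacing also scales with $d$) and ≈ −1.7 for the
soma-plus-dendrite cell over 10–40 µm (between the soma-dominated −1 and
sink-dominated −3 regimes); and the device energy $\tfrac12 C V_{th}^2$
rises with capacitance only up to ≈400 µF for the generic cell, falling at
700 µF where the slow 6.3 °C kinetics let the long underdamped pulse excite
anomalously cheaply (anode-break-type rebound), whereas faster realistic
membranes keep it rising.

## Problem sizes

The shipped tests and the acceptance script run the 339-compartment axon
for 5–35 ms of biological time at 1 µs steps, 11-point soma-shift sweeps of
a ~420-compartment myelinated cell, and a few hundred threshold
bisections on 10–50 compartment cells; the full suite completes in a few
minutes on one core. Larger morphologies (SWC imports) scale linearly in
compartments × steps.

## Worked example

```{r example, eval = FALSE}
co <- standard_coil()        # 2 cm, 30 turns, 1 cm standoff, one-radius shift
pulse <- standard_pulse()    # underdamped 0.09 Ohm / 13 uH / 200 uF
axon <- build_straight_axon(100, "16cm")

th <- find_magnetic_threshold(axon, co, pulse, resolution = 0.25,
                              config = sim_config(t_stop = 5, save_every = 5))
th$threshold                 # ~13691 V (physical SI scale; see above)

sim <- ms_run(axon, co, standard_pulse(th$hi),
              config = sim_config(t_stop = 35, save_every = 10))
initiation_site(sim)         # interior site, ~1.7 cm from the coil center
```
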