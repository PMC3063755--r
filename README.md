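# magstim

Biophysical simulation of magnetic stimulation (MS/TMS-style) of neurons in
R. A current-pulsed circular coil induces an electric field in the tissue;
`magstim` computes that field analytically from the loop vector potential,
drives a branched compartmental cable model with Hodgkin–Huxley
excitability through it, and provides the threshold-search and sweep
protocols used to study which neuronal elements magnetic pulses excite.

It is aimed at computational neuroscientists who want a self-contained,
scriptable alternative to wiring a field calculation into a general-purpose
simulator: the field, stimulator circuit, morphology, membrane, solver and
protocols live behind one R interface and are cross-checked against
independent oracles in the test suite.

## The model in brief

* **Coil field.** For a loop of radius $r$ at standoff $z$, the azimuthal
  vector potential per unit current is
  $A_\phi = \frac{\mu}{4\pi}\frac{4r}{\sqrt{(r+\rho)^2+z^2}}\,
  \frac{(2-m)K(m)-2E(m)}{m}$ with $m = 4r\rho/((r+\rho)^2+z^2)$; the induced
  field of an $N$-turn coil separates into $E(x,y,t) = S(x,y)\,
  \dot I(t)$ with $S = -N A_\phi \hat\phi$. Arbitrary coil paths are handled
  by Biot–Savart line-integral quadrature, which also serves as the test
  oracle for the closed form.
* **Stimulator.** Series RLC capacitor discharge (underdamped iff
  $R < 2\sqrt{L/C}$), $I(0)=0$, $\dot I(0)=V_0/L$; the charge voltage $V_0$
  is the "magnetic threshold" search variable.
* **Cable drive.** Only the field component along each neurite matters: each
  compartment receives the injected current
  $-\big(E_a^{\rm distal}-E_a^{\rm proximal}\big)/r_a$ (zero-reversal
  source), the discrete form of the activating function
  $\lambda^2\,\partial E_a/\partial a$. Backward-Euler time stepping (1 µs)
  with an exact Hines tree solve; classic 6.3 °C Hodgkin–Huxley, passive,
  and myelin mechanisms.
* **Protocols.** Spike detection, AP initiation-site localization,
  magnetic/current threshold bisection with bracket verification, and sweep
  drivers: threshold vs. fiber diameter, coil position, bend/bifurcation/
  diameter-step geometry, dendrite count, pulse duration (strength–duration
  and device energy), soma position of a myelinated cell, and neuronal state
  (EPSP / preceding spike).

See the methods vignette (`vignettes/magnetic-stimulation.Rmd`) for the
numerical scheme, parameter defaults, design decisions and limitations —
including why absolute thresholds come out on the physical kilovolt scale.

## Worked example

```r
library(magstim)

co    <- standard_coil()      # r = 2 cm, 30 turns, 1 cm standoff,
                              # center shifted one radius off the fiber line
pulse <- standard_pulse()     # underdamped: 0.09 Ohm, 13 uH, 200 uF
axon  <- build_straight_axon(diam = 100, length = "16cm")

locate_axon_hotspot(co) * 100
#> [1] 1.665        # cm from the coil center: max field gradient on the fiber

th <- find_magnetic_threshold(axon, co, pulse, resolution = 0.25,
                              config = sim_config(t_stop = 5, save_every = 5))
th
#> <ms_threshold> 1.369e+04 V (bracket [1.369e+04, 1.369e+04], 19 runs)

sim <- ms_run(axon, co, standard_pulse(th$hi),
              config = sim_config(t_stop = 35, save_every = 10))
initiation_site(sim)$pos      # spike starts at the hotspot, then two APs
                              # travel to the opposite fiber ends
```

The threshold (~13.7 kV on the capacitor, peak coil current ~54 kA / 30
turns) is the minimal stimulus for which any excitable compartment fires;
the action potential initiates where the along-fiber gradient of the
induced field is maximal (1.66 cm from the coil center, inside the 2 cm
coil radius), and two spikes propagate in opposite directions — the
classical signature of magnetic peripheral-nerve stimulation.

`run_experiment()` exposes the full sweep families, e.g.
`run_experiment("fig5_dendrites")` returns magnetic threshold, somatic
current threshold and input resistance for 1–11 dendrites (the three are
tightly correlated: dendrites act as current sinks).

A thin command-line wrapper over YAML run configs lives at
`inst/cli/magstim.R` (`simulate`, `threshold`, `experiment`,
`field-export`, `validate-config` subcommands).

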