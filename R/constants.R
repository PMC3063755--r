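# Pinned biophysical constants.
#
# The classic squid-axon Hodgkin-Huxley parameter set (rates at 6.3 degC)
# with the conventional shifted reversal potentials; these are the defaults
# every compartmental simulator ships for the "hh" mechanism.  All hh/passive
# simulations in the package start from these unless overridden.

HH_CONST <- list(
  gnabar = 0.120,    # S/cm^2
  gkbar  = 0.036,    # S/cm^2
  gl     = 0.0003,   # S/cm^2
  ena    =  50.0,    # mV
  ek     = -77.0,    # mV
  el     = -54.3,    # mV
  cm     = 1.0,      # uF/cm^2
  Ra     = 35.4,     # Ohm*cm, axial resistivity
  v_init = -65.0     # mV
)

# Passive-dendrite defaults (not printed in the source experiments; chosen
# as a standard 30 kOhm*cm^2 membrane at the hh resting potential, and
# configurable everywhere they are used).
PASSIVE_CONST <- list(
  g_pas = 1 / 30000,  # S/cm^2
  e_pas = -65.0,      # mV
  cm    = 1.0         # uF/cm^2
)

# Myelin: a purely capacitive sheath with no conductance, at the membrane's
# ordinary specific capacitance (what a compartment carries when no
# mechanism is inserted).  A thinner high-grade sheath can be modelled by
# lowering cm per mechanism override.
MYELIN_CONST <- list(
  g_pas = 0.0,
  e_pas = -65.0,
  cm    = 1.0         # uF/cm^2
)
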