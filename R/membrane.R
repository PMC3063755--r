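# Membrane mechanisms: classic Hodgkin-Huxley, passive leak, myelin.

#' Membrane mechanism specification
#'
#' @param kind one of `"hh"`, `"passive"`, `"myelin"`.
#' @param ... overrides of the mechanism's defaults: for `hh`, `gnabar`,
#'   `gkbar`, `gl` (S/cm^2), `ena`, `ek`, `el` (mV), `cm` (uF/cm^2) and
#'   `na_shift` (mV; shifts Na activation and inactivation along the voltage
#'   axis, negative = hyperpolarizing, lowering threshold); for `passive`
#'   and `myelin`, `g_pas` (S/cm^2), `e_pas` (mV), `cm`.
#' @return an object of class `ms_mechanism`.
#' @examples
#' mechanism("hh")
#' mechanism("passive", g_pas = 5e-5)
#' @export
mechanism <- function(kind = c("hh", "passive", "myelin"), ...) {
  kind <- match.arg(kind)
  ov <- list(...)
  m <- switch(kind,
    hh = list(kind = "hh", gnabar = HH_CONST$gnabar, gkbar = HH_CONST$gkbar,
              gl = HH_CONST$gl, ena = HH_CONST$ena, ek = HH_CONST$ek,
              el = HH_CONST$el, cm = HH_CONST$cm, na_shift = 0),
    passive = list(kind = "passive", g_pas = PASSIVE_CONST$g_pas,
                   e_pas = PASSIVE_CONST$e_pas, cm = PASSIVE_CONST$cm),
    myelin = list(kind = "myelin", g_pas = MYELIN_CONST$g_pas,
                  e_pas = MYELIN_CONST$e_pas, cm = MYELIN_CONST$cm))
  bad <- setdiff(names(ov), names(m))
  if (length(bad)) stop("unknown mechanism parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  m[names(ov)] <- ov
  gs <- unlist(m[intersect(names(m), c("gnabar", "gkbar", "gl", "g_pas"))])
  stopifnot(all(gs >= 0), m$cm > 0)
  structure(m, class = "ms_mechanism")
}

#' Default mechanism assignment by section tag
#'
#' Maps the builders' section tags to mechanisms: `soma`, `axon` and `node`
#' carry full Hodgkin-Huxley membrane, `dend` is passive, `myelin` is a
#' zero-conductance, low-capacitance insulator.
#'
#' @param ... named overrides, e.g. `dend = mechanism("passive", g_pas = 1e-4)`.
#' @return named list of `ms_mechanism` objects.
#' @export
default_mechanisms <- function(...) {
  m <- list(soma = mechanism("hh"), axon = mechanism("hh"),
            node = mechanism("hh"), dend = mechanism("passive"),
            myelin = mechanism("myelin"), hh = mechanism("hh"),
            passive = mechanism("passive"))
  ov <- list(...)
  m[names(ov)] <- ov
  m
}

#' Hodgkin-Huxley rate functions (6.3 degC)
#'
#' Classic squid-axon opening/closing rates in ms^-1, with the removable
#' singularities of the alpha functions evaluated by their analytic limits.
#' `na_shift` translates the m and h rate functions along the voltage axis.
#'
#' @param v membrane potential, mV (vectorized).
#' @param na_shift Na-kinetics voltage shift, mV.
#' @return list with `am, bm, ah, bh, an, bn`.
#' @export
hh_rates <- function(v, na_shift = 0) {
  vna <- v - na_shift
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  list(am = 0.1 * vtrap(-(vna + 40), 10),
       bm = 4 * exp(-(vna + 65) / 18),
       ah = 0.07 * exp(-(vna + 65) / 20),
       bh = 1 / (exp(-(vna + 35) / 10) + 1),
       an = 0.01 * vtrap(-(v + 55), 10),
       bn = 0.125 * exp(-(v + 65) / 80))
}

#' Steady-state Hodgkin-Huxley gating values
#'
#' @param v membrane potential, mV (vectorized).
#' @param na_shift Na-kinetics voltage shift, mV.
#' @return data.frame with columns `m`, `h`, `n` (values in (0, 1)).
#' @export
hh_steady_state <- function(v, na_shift = 0) {
  r <- hh_rates(v, na_shift)
  data.frame(m = r$am / (r$am + r$bm),
             h = r$ah / (r$ah + r$bh),
             n = r$an / (r$an + r$bn))
}

#' Ionic membrane current density of a mechanism
#'
#' Passive / myelin: `g_pas * (v - e_pas)`. Hodgkin-Huxley: the sum of
#' sodium, potassium and leak currents at the supplied gating state
#' (`gates` a list or data.frame with `m`, `h`, `n`; defaults to the
#' steady state at `v`). Positive = outward.
#'
#' @param mech an [mechanism()] object.
#' @param v membrane potential, mV.
#' @param gates gating values for `hh` (optional).
#' @return current density, mA/cm^2.
#' @export
membrane_current <- function(mech, v, gates = NULL) {
  stopifnot(inherits(mech, "ms_mechanism"))
  if (mech$kind != "hh") return(mech$g_pas * (v - mech$e_pas))
  if (is.null(gates)) gates <- hh_steady_state(v, mech$na_shift)
  ina <- mech$gnabar * gates$m^3 * gates$h * (v - mech$ena)
  ik <- mech$gkbar * gates$n^4 * (v - mech$ek)
  il <- mech$gl * (v - mech$el)
  ina + ik + il
}

#' Resting potential of a Hodgkin-Huxley membrane
#'
#' Root of the steady-state net ionic current.
#'
#' @param mech an `hh` [mechanism()].
#' @param interval search interval, mV.
#' @return resting potential, mV.
#' @export
hh_resting_potential <- function(mech = mechanism("hh"),
                                 interval = c(-90, -40)) {
  stopifnot(mech$kind == "hh")
  uniroot(function(v) membrane_current(mech, v), interval, tol = 1e-10)$root
}

#' Passive cable constants of a fiber
#'
#' For diameter `d` (um), axial resistivity `Ra` (Ohm*cm), membrane
#' resistance `Rm` (Ohm*cm^2) and capacitance `cm` (uF/cm^2):
#' `r_a = 4 Ra / (pi d^2)` (Ohm/cm), `r_m = Rm / (pi d)` (Ohm*cm),
#' `lambda = sqrt(r_m / r_a)` (converted to um), `tau = Rm * cm` (ms).
#' `lambda` scales as `sqrt(d)`.
#'
#' @param diam fiber diameter, um.
#' @param Ra axial resistivity, Ohm*cm.
#' @param Rm specific membrane resistance, Ohm*cm^2.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @return list with `r_a` (Ohm/cm), `r_m` (Ohm*cm), `lambda_um`, `tau_ms`.
#' @export
cable_constants <- function(diam, Ra = HH_CONST$Ra, Rm = 1 / PASSIVE_CONST$g_pas,
                            cm = 1) {
  d_cm <- diam * 1e-4
  r_a <- 4 * Ra / (pi * d_cm^2)
  r_m <- Rm / (pi * d_cm)
  list(r_a = r_a, r_m = r_m,
       lambda_um = sqrt(r_m / r_a) * 1e4,
       tau_ms = Rm * cm * 1e-3)
}
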