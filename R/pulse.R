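#' Series RLC stimulator parameters
#'
#' The magnetic stimulator is modeled as a capacitor charged to `V0`
#' discharging through the coil in a series RLC circuit. `V0` is the
#' stimulus strength and the variable of the magnetic-threshold search.
#' Unit-suffixed strings are accepted (`"13uH"`, `"200uF"`, `"0.09Ohm"`).
#'
#' @param V0 capacitor charge voltage, V.
#' @param R series resistance, Ohm.
#' @param L inductance, H.
#' @param C capacitance, F.
#' @return an object of class `ms_rlc`.
#' @examples
#' p <- rlc_params(V0 = 36, R = 0.09, L = "13uH", C = "200uF")
#' classify_mode(p)   # "underdamped"
#' @export
rlc_params <- function(V0, R, L, C) {
  V0 <- parse_quantity(V0); R <- parse_quantity(R)
  L <- parse_quantity(L);   C <- parse_quantity(C)
  stopifnot(V0 >= 0, R > 0, L > 0, C > 0)
  structure(list(V0 = V0, R = R, L = L, C = C), class = "ms_rlc")
}

#' @export
print.ms_rlc <- function(x, ...) {
  cat(sprintf("<ms_rlc> V0 = %g V, R = %g Ohm, L = %g uH, C = %g uF (%s)\n",
              x$V0, x$R, x$L * 1e6, x$C * 1e6, classify_mode(x)))
  invisible(x)
}

#' Damping regime of the RLC discharge
#'
#' Underdamped (oscillatory decaying current) iff `R < 2*sqrt(L/C)`; the
#' critically damped boundary `R = 2*sqrt(L/C)` is classified as overdamped.
#'
#' @param params an [rlc_params()] object.
#' @return `"underdamped"` or `"overdamped"`.
#' @export
classify_mode <- function(params) {
  stopifnot(inherits(params, "ms_rlc"))
  if (params$R < 2 * sqrt(params$L / params$C)) "underdamped" else "overdamped"
}

#' Coil current and its time derivative for the RLC discharge
#'
#' Closed-form solution of `L I' + R I + Q/C = 0` with `Q(0) = C V0`,
#' `I(0) = 0`, so that `dI/dt(0) = V0/L`. With `alpha = R/(2L)` and
#' `w0^2 = 1/(LC)`: underdamped, `I = V0/(wL) exp(-alpha t) sin(w t)` with
#' `w = sqrt(w0^2 - alpha^2)`; overdamped,
#' `I = V0/(2 beta L) (exp(s1 t) - exp(s2 t))` with `beta =
#' sqrt(alpha^2 - w0^2)`, `s12 = -alpha +/- beta` (the critically damped
#' limit `beta = 0` is evaluated by its closed form `(V0/L) t exp(-alpha t)`).
#' `dIdt` is the exact analytic derivative of `I`.
#'
#' @param t time(s) since discharge onset, s (t >= 0).
#' @param params an [rlc_params()] object.
#' @return list with numeric vectors `I` (A) and `dIdt` (A/s).
#' @export
waveform <- function(t, params) {
  stopifnot(inherits(params, "ms_rlc"), all(t >= 0))
  V0 <- params$V0; R <- params$R; L <- params$L; C <- params$C
  alpha <- R / (2 * L)
  w0sq <- 1 / (L * C)
  disc <- alpha^2 - w0sq
  if (disc < 0) {                      # underdamped
    w <- sqrt(-disc)
    e <- exp(-alpha * t)
    I <- V0 / (w * L) * e * sin(w * t)
    dIdt <- V0 / (w * L) * e * (w * cos(w * t) - alpha * sin(w * t))
  } else if (disc == 0) {              # critically damped limit
    e <- exp(-alpha * t)
    I <- V0 / L * t * e
    dIdt <- V0 / L * e * (1 - alpha * t)
  } else {                             # overdamped
    beta <- sqrt(disc)
    s1 <- -alpha + beta; s2 <- -alpha - beta
    I <- V0 / (2 * beta * L) * (exp(s1 * t) - exp(s2 * t))
    dIdt <- V0 / (2 * beta * L) * (s1 * exp(s1 * t) - s2 * exp(s2 * t))
  }
  list(I = I, dIdt = dIdt)
}

#' Energy initially stored in the stimulator capacitor
#'
#' `E = C V0^2 / 2`, the device energy required per pulse.
#'
#' @param params an [rlc_params()] object.
#' @return energy in joules.
#' @export
device_energy <- function(params) {
  stopifnot(inherits(params, "ms_rlc"))
  0.5 * params$C * params$V0^2
}

#' Effective pulse duration
#'
#' A documented duration metric, monotone in `C` at fixed R, L: one full
#' oscillation period `2*pi/w` for the underdamped regime; for the
#' overdamped regime, the time at which `|I|` has decayed to 5 % of its peak
#' (found numerically on the closed form).
#'
#' @param params an [rlc_params()] object.
#' @return duration in seconds.
#' @export
effective_duration <- function(params) {
  stopifnot(inherits(params, "ms_rlc"))
  alpha <- params$R / (2 * params$L)
  w0sq <- 1 / (params$L * params$C)
  if (classify_mode(params) == "underdamped") {
    2 * pi / sqrt(w0sq - alpha^2)
  } else {
    p <- params
    if (p$V0 == 0) p$V0 <- 1   # duration is amplitude-independent
    t_peak <- optimize(function(t) -abs(waveform(t, p)$I),
                       c(0, 20 / alpha))$minimum
    peak <- abs(waveform(t_peak, p)$I)
    uniroot(function(t) abs(waveform(t, p)$I) - 0.05 * peak,
            c(t_peak, 200 / min(alpha, sqrt(w0sq))))$root
  }
}

#' Sampled pulse trace
#'
#' Convenience wrapper evaluating [waveform()] on a regular time base.
#'
#' @param params an [rlc_params()] object.
#' @param dt sample interval, s; @param t_stop end time, s.
#' @return an `ms_pulse_trace`: list(mode, times, current, dcurrent).
#' @export
pulse_trace <- function(params, dt = 1e-6, t_stop = 2e-3) {
  t <- seq(0, t_stop, by = dt)
  w <- waveform(t, params)
  structure(list(mode = classify_mode(params), times = t,
                 current = w$I, dcurrent = w$dIdt, params = params),
            class = "ms_pulse_trace")
}
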