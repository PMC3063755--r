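# Shared fixtures and independent oracles for the test suite.

std_coil <- function(...) standard_coil(...)
std_pulse <- function(...) standard_pulse(...)

# Biot-Savart line-integral oracle for the loop vector potential, written
# directly from the current-element sum (independent of the package's
# closed form and of line_integral_field()).
oracle_loop_A <- function(rho, z, r, n = 2e4, mu = 4e-7 * pi) {
  th <- (seq_len(n) - 0.5) / n * 2 * pi
  dly <- r * cos(th) * (2 * pi / n)          # y-component of dl
  R <- sqrt((rho - r * cos(th))^2 + (r * sin(th))^2 + z^2)
  sum(dly / R) * mu / (4 * pi)               # A_phi at (rho, 0, z)
}

# RLC discharge solved numerically: L q'' + R q' + q/C = 0, q(0) = C V0.
oracle_rlc <- function(params, times) {
  f <- function(t, y, p) list(c(y[2], -(p$R * y[2] + y[1] / p$C) / p$L))
  out <- deSolve::ode(y = c(q = params$C * params$V0, dq = 0),
                      times = times, func = f, parms = params,
                      rtol = 1e-10, atol = 1e-12)
  list(I = -out[, "dq"],
       t = out[, "time"])
}

# small SWC fixture written to a temp file
write_swc_text <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# a small excitable cell used across protocol tests
soma_cell <- function(n_dend = 1) build_soma_dendrites(20, 1, n_dend, 600)

hotspot_cell <- function(n_dend = 1) {
  place(soma_cell(n_dend), offset = c(-locate_axon_hotspot(std_coil()) * 1e6, 0))
}
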