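# Simulation engine: induced drive, activating function, time integration.

#' Induced transmembrane current per compartment, per unit dI/dt
#'
#' Difference form of the induced axial drive. Along each section's path the
#' tangential field `E_a = E . t_hat` is evaluated at the compartment
#' boundary nodes, with the node tangent `t_hat` taken as the compartment
#' chord at section ends and the (normalized) mean of the two adjacent
#' chords at interior nodes. The injected membrane current of a compartment
#' with axial resistance per unit length `r_a` is then
#' `-(E_a(distal node) - E_a(proximal node)) / r_a`, a pure source with
#' zero reversal (independent of membrane potential), positive =
#' depolarizing. The differences telescope along a section, so a spatially
#' constant field along a straight uniform fiber produces zero drive
#' everywhere, a segment running radially from the coil axis receives none
#' (the field is purely tangential), and a bend inside a section receives
#' the localized drive `E . (a2_hat - a1_hat)` that the directional
#' discontinuity of `E_a` implies. Differences are taken within sections
#' only; branch points add no extra term.
#'
#' @param compiled an `ms_compiled` (or an `ms_neuron`, compiled with
#'   defaults).
#' @param coil an [coil()] object.
#' @param mech_map,config used only when `compiled` is a raw neuron.
#' @return numeric vector, nA per (A/s) of coil-current slew rate.
#' @export
induced_segment_currents <- function(compiled, coil,
                                     mech_map = default_mechanisms(),
                                     config = sim_config()) {
  if (inherits(compiled, "ms_neuron"))
    compiled <- compile_neuron(compiled, mech_map, config)
  stopifnot(inherits(compiled, "ms_compiled"), inherits(coil, "ms_coil"))
  cp <- compiled$comp
  n <- nrow(cp)
  dvec <- cbind(cp$x1 - cp$x0, cp$y1 - cp$y0, cp$z1 - cp$z0)
  len <- sqrt(rowSums(dvec^2))
  # a sharp fold can make a spanning compartment's chord vanish; no
  # projection direction exists there
  len[len < 1e-9] <- Inf
  a_hat <- dvec / len
  out <- numeric(n)
  r_a_SI <- 4 * (compiled$Ra / 100) / (pi * (cp$diam * 1e-6)^2)  # Ohm/m
  for (idx in compiled$sec_comps) {
    k <- length(idx)
    # node positions (um -> m) and node tangents along this section's path
    npos <- rbind(cbind(cp$x0[idx], cp$y0[idx]),
                  cbind(cp$x1[idx[k]], cp$y1[idx[k]]))[, , drop = FALSE] * 1e-6
    tg <- a_hat[idx, , drop = FALSE]
    tnode <- rbind(tg[1, ], (tg[-k, , drop = FALSE] + tg[-1, , drop = FALSE]),
                   tg[k, ])
    if (k == 1) tnode <- rbind(tg[1, ], tg[1, ])
    tlen <- sqrt(rowSums(tnode^2))
    tlen[tlen < 1e-9] <- Inf
    tnode <- tnode / tlen
    S <- spatial_field(npos, coil)
    Ea <- S[, 1] * tnode[, 1] + S[, 2] * tnode[, 2]
    out[idx] <- -(Ea[-1] - Ea[-(k + 1)]) / r_a_SI[idx] * 1e9
  }
  out
}

#' Activating-function profile along a neuron
#'
#' Per-compartment steady-state polarization drive
#' `lambda^2 * dE_a/da` (finite difference along the path), per unit of the
#' temporal factor dI/dt. `lambda` uses each compartment's membrane
#' resistance (1/g_leak for Hodgkin-Huxley membrane, 1/g_pas for passive;
#' infinite for zero-conductance myelin, for which the profile is reported
#' as NA).
#'
#' @inheritParams induced_segment_currents
#' @return numeric vector, mV per (A/s); sign: positive = depolarizing.
#' @export
activating_function_profile <- function(compiled, coil,
                                        mech_map = default_mechanisms(),
                                        config = sim_config()) {
  if (inherits(compiled, "ms_neuron"))
    compiled <- compile_neuron(compiled, mech_map, config)
  cp <- compiled$comp
  i_nA <- induced_segment_currents(compiled, coil)
  # lambda^2 dEa/da = r_m/r_a * dEa/da = i_per_len * r_m  (per unit dIdt)
  g_spec <- compiled$gl_uS / (compiled$area_cm2 * 1e6)   # S/cm^2
  r_m <- ifelse(g_spec > 0, 1 / g_spec, NA_real_) / (pi * cp$diam * 1e-4)
  i_per_len <- (i_nA * 1e-9) / (cp$L * 1e-4)             # A/cm per (A/s)
  i_per_len * r_m * 1e3                                   # mV per (A/s)
}

#' Run a magnetic-stimulation (or current-injection) simulation
#'
#' Assembles the compartmental system, initializes the membrane at
#' `config$v_init` with gating variables at steady state, and integrates the
#' branched cable equation with ionic, capacitive, synaptic, electrode and
#' induced currents by the implicit backward-Euler scheme with a direct tree
#' solve per step. The induced drive is the per-compartment difference
#' current scaled by the analytic dI/dt of the RLC pulse evaluated at each
#' step midpoint. Branch points conserve axial current; terminals are sealed
#' ends.
#'
#' @param neuron an `ms_neuron` (or a prebuilt `ms_compiled`).
#' @param coil an [coil()] or NULL for no magnetic drive.
#' @param pulse an [rlc_params()] or NULL.
#' @param mech_map named list tag -> [mechanism()].
#' @param config an [sim_config()].
#' @return `ms_sim`: list with `times` (ms), `v` (matrix, recorded sites x
#'   times, mV), `comp` (data.frame describing recorded compartments),
#'   `rec_idx`, `config`.
#' @export
ms_run <- function(neuron, coil = NULL, pulse = NULL,
                   mech_map = default_mechanisms(), config = sim_config()) {
  compiled <- if (inherits(neuron, "ms_compiled")) neuron
              else compile_neuron(neuron, mech_map, config)
  n <- nrow(compiled$comp)
  nsteps <- ceiling(config$t_stop / config$dt)
  if (!is.null(coil) && !is.null(pulse)) {
    if (!all(abs(c(compiled$comp$z0, compiled$comp$z1)) < 1e-9))
      stop("planar field drive requires a planar neuron (all z = 0)",
           call. = FALSE)
    induced <- induced_segment_currents(compiled, coil)
    t_mid_s <- ((seq_len(nsteps) - 0.5) * config$dt - config$pulse_delay) * 1e-3
    dIdt <- numeric(nsteps)
    on <- t_mid_s >= 0
    if (any(on)) dIdt[on] <- waveform(t_mid_s[on], pulse)$dIdt
  } else {
    induced <- numeric(n)
    dIdt <- numeric(nsteps)
  }
  rec_idx <- if (identical(config$record, "all")) seq_len(n)
             else vapply(config$record, function(s)
               site_to_comp(compiled, s[[1]], s[[2]]), integer(1))
  ic <- config$iclamp
  syn <- config$synapses
  out <- simulate_cable_cpp(
    parent = compiled$parent0, g_parent = compiled$g_parent_uS,
    cap_nF = compiled$cap_nF, gna_uS = compiled$gna_uS,
    gk_uS = compiled$gk_uS, gl_uS = compiled$gl_uS,
    ena = compiled$ena, ek = compiled$ek, el = compiled$el,
    na_shift = compiled$na_shift, active = compiled$active,
    induced_nA = induced, dIdt = dIdt,
    v_init = config$v_init, dt = config$dt, nsteps = nsteps,
    ic_comp = vapply(ic, function(e)
      site_to_comp(compiled, e$section, e$pos) - 1L, integer(1)),
    ic_amp = vapply(ic, function(e) e$amp, numeric(1)),
    ic_start = vapply(ic, function(e) e$start, numeric(1)),
    ic_dur = vapply(ic, function(e) e$dur, numeric(1)),
    syn_comp = vapply(syn, function(e)
      site_to_comp(compiled, e$section, e$pos) - 1L, integer(1)),
    syn_onset = vapply(syn, function(e) e$onset, numeric(1)),
    syn_gmax = vapply(syn, function(e) e$gmax, numeric(1)),
    syn_tau = vapply(syn, function(e) e$tau, numeric(1)),
    syn_erev = vapply(syn, function(e) e$erev, numeric(1)),
    record = rec_idx - 1L, save_every = config$save_every)
  structure(list(times = out$times, v = out$v,
                 comp = compiled$comp[rec_idx, , drop = FALSE],
                 rec_idx = rec_idx, config = config),
            class = "ms_sim")
}

#' @export
print.ms_sim <- function(x, ...) {
  cat(sprintf("<ms_sim> %d sites x %d samples, t = [0, %.3g] ms, v in [%.3g, %.3g] mV\n",
              nrow(x$v), ncol(x$v), max(x$times), min(x$v), max(x$v)))
  invisible(x)
}

#' Export recorded traces as delimited text
#'
#' Time column plus one column per recorded site (named
#' `sec<section>_pos<pos>`), tab-separated.
#'
#' @param sim an `ms_sim`; @param path output path.
#' @export
write_sim <- function(sim, path) {
  df <- data.frame(time_ms = sim$times, t(sim$v))
  names(df)[-1] <- sprintf("sec%d_pos%.3f", sim$comp$section, sim$comp$pos)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady-state input resistance at a site
#'
#' Applies a small current step at the site, waits for steady state, and
#' returns `dV_ss / dI` in megaohms. A symmetry check with the opposite-sign
#' step warns if the response is outside the linear regime.
#'
#' @param neuron an `ms_neuron`.
#' @param site `c(section, pos)`.
#' @param step_amplitude step current, nA (default -0.01, hyperpolarizing).
#' @param mech_map mechanism assignment.
#' @param settle,dur settle time before and duration of the step, ms.
#' @param dt integration step, ms (the default is coarser than for spiking
#'   simulations; the approach to steady state is slow and smooth).
#' @param check_linearity run the opposite step and warn on asymmetry > 2%.
#' @return input resistance, MOhm.
#' @export
input_resistance <- function(neuron, site = c(1, 0.5),
                             step_amplitude = -0.01,
                             mech_map = default_mechanisms(),
                             settle = 20, dur = 150, dt = 0.01,
                             check_linearity = FALSE) {
  one <- function(amp) {
    cfg <- sim_config(dt = dt, t_stop = settle + dur,
                      record = list(site), save_every = 10L,
                      iclamp = list(list(section = site[[1]], pos = site[[2]],
                                         amp = amp, start = settle,
                                         dur = dur + 1)))   # still on at t_stop
    sim <- ms_run(neuron, mech_map = mech_map, config = cfg)
    v0 <- sim$v[1, max(which(sim$times < settle))]  # last pre-step sample
    v1 <- sim$v[1, ncol(sim$v)]
    (v1 - v0) / amp
  }
  r <- one(step_amplitude)
  if (check_linearity) {
    r2 <- one(-step_amplitude)
    if (abs(r - r2) > 0.02 * abs(r))
      warning("input-resistance step outside the linear regime ",
              "(asymmetry ", sprintf("%.1f", 100 * abs(r - r2) / abs(r)),
              "%)", call. = FALSE)
  }
  r
}
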