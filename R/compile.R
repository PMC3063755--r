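# Spatial discretization: neuron sections -> solver compartments.

#' Simulation configuration
#'
#' @param dt integration time step, ms (default 0.001 = 1 us).
#' @param t_stop simulation end time, ms.
#' @param record `"all"` (every compartment) or a list of `c(section, pos)`
#'   recording sites (section index, normalized position 0-1).
#' @param save_every store every k-th time step (thinning of the output
#'   only; integration always uses `dt`).
#' @param pulse_delay delay of the magnetic pulse onset, ms; the membrane
#'   sits at its initialized state before onset.
#' @param v_init initialization potential, mV; gating variables start at
#'   their steady state for this voltage.
#' @param iclamp list of current-clamp electrodes, each
#'   `list(section, pos, amp, start, dur)` (nA, ms).
#' @param synapses list of alpha-conductance synapses, each
#'   `list(section, pos, onset, gmax, tau, erev)` (ms, uS, ms, mV).
#' @param d_lambda spatial-resolution rule: compartment length at most
#'   `d_lambda` times the AC length constant at `f_lambda` Hz.
#' @param f_lambda frequency (Hz) of the discretization rule.
#' @param max_seg_um optional hard cap on compartment length, um.
#' @return a list of class `ms_config`.
#' @export
sim_config <- function(dt = 0.001, t_stop = 5, record = "all",
                       save_every = 1L, pulse_delay = 0, v_init = -65,
                       iclamp = list(), synapses = list(),
                       d_lambda = 0.1, f_lambda = 100, max_seg_um = Inf) {
  stopifnot(dt > 0, t_stop > 0, t_stop >= pulse_delay)
  structure(list(dt = dt, t_stop = t_stop, record = record,
                 save_every = as.integer(save_every),
                 pulse_delay = pulse_delay, v_init = v_init,
                 iclamp = iclamp, synapses = synapses,
                 d_lambda = d_lambda, f_lambda = f_lambda,
                 max_seg_um = max_seg_um),
            class = "ms_config")
}

# AC length constant at frequency f (Hz), um; the usual d_lambda rule.
lambda_f_um <- function(diam_um, Ra, cm, f) {
  1e5 * sqrt(diam_um / (4 * pi * f * Ra * cm))
}

#' Discretize a neuron into solver compartments
#'
#' Splits every section polyline into compartments no longer than
#' `d_lambda` times the 100 Hz AC length constant (and no longer than
#' `max_seg_um`), never spanning a bend. Returns the compartment table and
#' the absolute electrical quantities the solver consumes.
#'
#' @param neuron an `ms_neuron`.
#' @param mech_map named list tag -> [mechanism()], see
#'   [default_mechanisms()].
#' @param config an [sim_config()].
#' @return a list of class `ms_compiled`: `comp` (data.frame with section,
#'   pos, endpoints, diameter, length, tag), `parent0` (0-based parent
#'   index), `g_parent_uS`, `cap_nF`, `gna_uS`, `gk_uS`, `gl_uS`, `ena`,
#'   `ek`, `el`, `na_shift`, `active`, `Ra`.
#' @export
compile_neuron <- function(neuron, mech_map = default_mechanisms(),
                           config = sim_config()) {
  stopifnot(inherits(neuron, "ms_neuron"))
  secs <- neuron$sections
  Ra <- neuron$Ra
  comp_rows <- list()
  parent0 <- integer(0)
  sec_comps <- vector("list", length(secs))   # compartment indices per section
  for (si in seq_along(secs)) {
    s <- secs[[si]]
    mech <- mech_map[[s$tag]]
    if (is.null(mech))
      stop("no mechanism mapped for section tag '", s$tag, "'", call. = FALSE)
    target <- min(config$d_lambda * lambda_f_um(s$diam, Ra, mech$cm,
                                                config$f_lambda),
                  config$max_seg_um)
    pts <- s$points
    edges <- diff(pts)
    elen <- sqrt(rowSums(edges^2))
    total <- sum(elen)
    cum0 <- c(0, cumsum(elen))
    # equal-arc-length compartments over the whole polyline; a compartment
    # may span a bend (its field projection then uses the chord direction,
    # which is what creates the localized bend drive of the difference
    # scheme); arc length is used for axial resistance and membrane area
    nseg <- max(1L, ceiling(total / target))
    if (nseg %% 2L == 0L) nseg <- nseg + 1L   # odd, so a midpoint bend is
                                              # interior to a compartment
    interp3 <- function(sl) {
      e <- findInterval(sl, cum0, rightmost.closed = TRUE)
      e <- min(e, nrow(edges))
      pts[e, ] + edges[e, ] * (sl - cum0[e]) / elen[e]
    }
    idx_here <- integer(0)
    prev <- NA_integer_
    for (k in seq_len(nseg)) {
      s0 <- total * (k - 1) / nseg
      s1 <- total * k / nseg
      p0 <- interp3(s0)
      p1 <- interp3(s1)
      comp_rows[[length(comp_rows) + 1L]] <-
        data.frame(section = si, pos = (s0 + s1) / 2 / total,
                   x0 = p0[1], y0 = p0[2], z0 = p0[3],
                   x1 = p1[1], y1 = p1[2], z1 = p1[3],
                   diam = s$diam, L = total / nseg, tag = s$tag)
      ci <- length(comp_rows)
      if (is.na(prev)) {
        if (s$parent == 0L) parent0[ci] <- -1L
        else {
          pc <- sec_comps[[s$parent]]
          ppos <- vapply(comp_rows[pc], function(r) r$pos, numeric(1))
          parent0[ci] <- pc[which.min(abs(ppos - s$parent_pos))] - 1L
        }
      } else parent0[ci] <- prev - 1L
      prev <- ci
      idx_here <- c(idx_here, ci)
    }
    sec_comps[[si]] <- idx_here
  }
  comp <- do.call(rbind, comp_rows)
  n <- nrow(comp)
  # electrical quantities
  area_cm2 <- pi * (comp$diam * 1e-4) * (comp$L * 1e-4)
  r_a_ohm_per_cm <- 4 * Ra / (pi * (comp$diam * 1e-4)^2)
  R_half <- r_a_ohm_per_cm * (comp$L * 1e-4) / 2      # Ohm
  g_parent_uS <- numeric(n)
  for (i in seq_len(n)) {
    if (parent0[i] >= 0) {
      g_parent_uS[i] <- 1e6 / (R_half[i] + R_half[parent0[i] + 1L])
    }
  }
  cap_nF <- gna <- gk <- gl <- ena <- ek <- el <- nash <- numeric(n)
  active <- logical(n)
  for (i in seq_len(n)) {
    m <- mech_map[[comp$tag[i]]]
    cap_nF[i] <- m$cm * area_cm2[i] * 1e3
    if (m$kind == "hh") {
      active[i] <- TRUE
      gna[i] <- m$gnabar * area_cm2[i] * 1e6
      gk[i] <- m$gkbar * area_cm2[i] * 1e6
      gl[i] <- m$gl * area_cm2[i] * 1e6
      ena[i] <- m$ena; ek[i] <- m$ek; el[i] <- m$el
      nash[i] <- m$na_shift
    } else {
      gl[i] <- m$g_pas * area_cm2[i] * 1e6
      el[i] <- m$e_pas
    }
  }
  comp$active <- active
  structure(list(comp = comp, parent0 = parent0, g_parent_uS = g_parent_uS,
                 cap_nF = cap_nF, gna_uS = gna, gk_uS = gk, gl_uS = gl,
                 ena = ena, ek = ek, el = el, na_shift = nash,
                 active = active, area_cm2 = area_cm2, Ra = Ra,
                 sec_comps = sec_comps),
            class = "ms_compiled")
}

# map a (section, pos) site to a compartment index
site_to_comp <- function(compiled, section, pos) {
  idx <- compiled$sec_comps[[section]]
  idx[which.min(abs(compiled$comp$pos[idx] - pos))]
}
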