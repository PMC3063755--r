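# Protocols: spike detection, initiation site, threshold searches, sweeps.

#' Detect action potentials in a voltage trace
#'
#' Upward crossings of the criterion voltage separated by at least
#' `min_isi` ms.
#'
#' @param trace numeric voltage trace, mV.
#' @param times matching time base, ms.
#' @param criterion spike criterion, mV (default 0).
#' @param min_isi minimal separation between detected spikes, ms.
#' @return numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(trace, times, criterion = 0, min_isi = 1) {
  stopifnot(length(trace) == length(times), all(is.finite(trace)))
  up <- which(trace[-1] >= criterion & trace[-length(trace)] < criterion)
  if (length(up) == 0) return(numeric(0))
  tt <- times[up + 1]
  keep <- c(TRUE, diff(tt) >= min_isi)
  tt[keep]
}

#' Localize the action-potential initiation site
#'
#' Site of the earliest criterion crossing in a full spatiotemporal
#' recording; ties within one saved step are broken by the largest dV/dt at
#' crossing. Returns a no-spike marker rather than an error so that sweeps
#' can record censored points.
#'
#' @param sim an `ms_sim` recorded with `record = "all"`.
#' @param criterion spike criterion, mV.
#' @return list with `spike` (logical), and when `spike` is TRUE: `section`,
#'   `pos`, `comp` (row index into `sim$comp`), `tag`, `time` (ms).
#' @export
initiation_site <- function(sim, criterion = 0) {
  stopifnot(inherits(sim, "ms_sim"))
  rows <- which(if (!is.null(sim$comp$active)) sim$comp$active else
    rep(TRUE, nrow(sim$v)))
  v <- sim$v[rows, , drop = FALSE]
  crossed <- v >= criterion
  first <- apply(crossed, 1, function(r) {
    w <- which(r & !c(FALSE, r[-length(r)]))
    if (length(w)) w[1] else NA_integer_
  })
  if (all(is.na(first))) return(list(spike = FALSE))
  t0 <- min(first, na.rm = TRUE)
  cand <- which(first == t0)
  if (length(cand) > 1) {
    dvdt <- (v[cand, t0] - v[cand, t0 - 1])
    cand <- cand[which.max(dvdt)]
  }
  cand <- rows[cand]
  list(spike = TRUE, section = sim$comp$section[cand],
       pos = sim$comp$pos[cand], comp = cand, tag = sim$comp$tag[cand],
       time = sim$times[t0])
}

# any excitable compartment reaches the criterion within the window; used by
# the threshold searches (v starts below criterion, so reaching it is a
# crossing). Passive and myelinated compartments are excluded: they can be
# polarized across the criterion directly by the induced drive without any
# regenerative event.
fired <- function(sim, criterion = 0, after = 0) {
  sel <- sim$times >= after
  rows <- if (!is.null(sim$comp$active)) sim$comp$active else
    rep(TRUE, nrow(sim$v))
  any(sim$v[rows, sel, drop = FALSE] >= criterion)
}

bisect_threshold <- function(test, bounds, resolution, cap) {
  lo <- bounds[1]; hi <- bounds[2]
  trace <- data.frame(value = numeric(0), fired = logical(0))
  try_one <- function(x) {
    f <- test(x)
    trace[nrow(trace) + 1L, ] <<- list(x, f)
    f
  }
  # verify / expand the bracket
  while (!try_one(hi)) {
    lo <- hi; hi <- hi * 2
    if (hi > cap)
      return(list(threshold = NA_real_, unexcitable = TRUE, trace = trace))
  }
  if (try_one(lo)) {
    while (lo > resolution && try_one(lo / 2)) lo <- lo / 2
    hi <- lo; lo <- max(lo / 2, 0)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (try_one(mid)) hi <- mid else lo <- mid
  }
  list(threshold = (lo + hi) / 2, lo = lo, hi = hi, unexcitable = FALSE,
       trace = trace)
}

#' Magnetic threshold of a neuron
#'
#' Minimal capacitor voltage `V0` of the RLC pulse that elicits an action
#' potential anywhere in the neuron, found by bisection to `resolution`
#' after verifying (and if necessary expanding) the bracket. The reported
#' threshold is the midpoint of the final bracket.
#'
#' @param neuron an `ms_neuron`.
#' @param coil an [coil()] object.
#' @param pulse_template an [rlc_params()]; its `V0` is overridden by the
#'   search variable.
#' @param bounds initial search bracket, volts.
#' @param resolution bracket width at which the search stops, volts.
#' @param cap give up and report unexcitable above this voltage.
#' @param mech_map,config passed to [ms_run()].
#' @param criterion spike criterion, mV.
#' @param spike_after only count criterion crossings at or after this time
#'   (ms); lets state-dependence protocols ignore the conditioning response.
#' @return `ms_threshold`: list with `threshold` (V; NA if unexcitable),
#'   `lo`, `hi`, `resolution`, `unexcitable`, `trace` (tested values and
#'   outcomes).
#' @export
find_magnetic_threshold <- function(neuron, coil, pulse_template,
                                    bounds = c(2000, 32000), resolution = 0.25,
                                    cap = 2e6,
                                    mech_map = default_mechanisms(),
                                    config = sim_config(),
                                    criterion = 0,
                                    spike_after = config$pulse_delay) {
  compiled <- compile_neuron(neuron, mech_map, config)
  test <- function(V0) {
    p <- pulse_template; p$V0 <- V0
    fired(ms_run(compiled, coil, p, mech_map, config), criterion, spike_after)
  }
  res <- bisect_threshold(test, bounds, resolution, cap)
  res$resolution <- resolution
  res$unit <- "V"
  class(res) <- "ms_threshold"
  res
}

#' Somatic current threshold of a neuron
#'
#' Minimal amplitude of a square current pulse injected at `site` that
#' elicits an action potential; bisection as in
#' [find_magnetic_threshold()].
#'
#' @param neuron an `ms_neuron`.
#' @param site `c(section, pos)` of the electrode.
#' @param pulse_duration square-pulse duration, ms.
#' @param bounds initial bracket, nA; @param resolution stop width, nA.
#' @param cap unexcitable above this amplitude, nA.
#' @param mech_map mechanisms; @param config simulation settings (its
#'   `iclamp` is replaced by the search electrode).
#' @param criterion spike criterion, mV.
#' @return `ms_threshold` with `threshold` in nA.
#' @export
find_current_threshold <- function(neuron, site = c(1, 0.5),
                                   pulse_duration = 5,
                                   bounds = c(0.05, 51.2), resolution = 0.005,
                                   cap = 1e4,
                                   mech_map = default_mechanisms(),
                                   config = sim_config(dt = 0.005,
                                                       t_stop = 10),
                                   criterion = 0) {
  compiled <- compile_neuron(neuron, mech_map, config)
  test <- function(amp) {
    cfg <- config
    cfg$iclamp <- list(list(section = site[[1]], pos = site[[2]], amp = amp,
                            start = 1, dur = pulse_duration))
    fired(ms_run(compiled, mech_map = mech_map, config = cfg), criterion)
  }
  res <- bisect_threshold(test, bounds, resolution, cap)
  res$resolution <- resolution
  res$unit <- "nA"
  class(res) <- "ms_threshold"
  res
}

#' @export
print.ms_threshold <- function(x, ...) {
  if (x$unexcitable) cat("<ms_threshold> unexcitable at cap\n")
  else cat(sprintf("<ms_threshold> %.4g %s (bracket [%.4g, %.4g], %d runs)\n",
                   x$threshold, x$unit, x$lo, x$hi, nrow(x$trace)))
  invisible(x)
}
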