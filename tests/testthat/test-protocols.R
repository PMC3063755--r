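test_that("spike detection finds criterion crossings with refractory spacing", {
  t <- seq(0, 20, by = 0.1)
  expect_length(detect_spikes(rep(-65, length(t)), t), 0)
  # two synthetic depolarizations crossing 0 mV, 5 ms apart
  tr <- -65 + 80 * (exp(-(t - 5)^2 / 0.2) + exp(-(t - 10)^2 / 0.2))
  expect_equal(length(detect_spikes(tr, t)), 2)
  expect_equal(detect_spikes(tr, t), c(4.8, 9.8), tolerance = 0.05)
  # crossings closer than min_isi merge
  tr2 <- -65 + 80 * (exp(-(t - 5)^2 / 0.002) + exp(-(t - 5.4)^2 / 0.002))
  expect_equal(length(detect_spikes(tr2, t, min_isi = 1)), 1)
})

test_that("zero-amplitude stimulation reports no spike, not an error", {
  cell <- hotspot_cell(1)
  sim <- ms_run(cell, standard_coil(), standard_pulse(0),
                config = sim_config(t_stop = 2, save_every = 10L))
  res <- initiation_site(sim)
  expect_false(res$spike)
})

test_that("threshold searches bracket and match a brute-force scan", {
  cell <- soma_cell(1)
  res <- find_current_threshold(cell, resolution = 0.002)
  expect_false(res$unexcitable)
  # bracketing: every tested value below lo failed, every value above hi fired
  expect_true(all(res$trace$fired[res$trace$value >= res$hi]))
  expect_true(all(!res$trace$fired[res$trace$value <= res$lo]))
  expect_lt(res$hi - res$lo, 0.002 + 1e-12)
  # brute-force scan oracle at the bisection resolution
  grid <- seq(res$threshold - 0.02, res$threshold + 0.02, by = 0.002)
  fired_grid <- vapply(grid, function(a) {
    cfg <- sim_config(dt = 0.005, t_stop = 10,
                      iclamp = list(list(section = 1, pos = 0.5, amp = a,
                                         start = 1, dur = 5)))
    sim <- ms_run(cell, config = cfg)
    max(sim$v) >= 0
  }, logical(1))
  scan_th <- grid[which(fired_grid)[1]]
  expect_lt(abs(res$threshold - scan_th), 2 * 0.002)
  # monotone firing along the scan (threshold well-defined)
  expect_true(all(diff(fired_grid) >= 0))
})

test_that("magnetic-threshold bisection equals a voltage scan", {
  co <- standard_coil()
  cell <- hotspot_cell(1)
  cfg <- sim_config(t_stop = 5, save_every = 5L)
  res <- find_magnetic_threshold(cell, co, standard_pulse(),
                                 resolution = 256, config = cfg)
  grid <- seq(res$threshold - 1024, res$threshold + 1024, by = 256)
  fired_grid <- vapply(grid, function(v0) {
    sim <- ms_run(cell, co, standard_pulse(v0), config = cfg)
    any(sim$v[sim$comp$active, ] >= 0)
  }, logical(1))
  expect_lt(abs(res$threshold - grid[which(fired_grid)[1]]), 2 * 256)
})

test_that("an inexcitable neuron reports unexcitable-at-cap", {
  fiber <- build_straight_axon(10, 2000)
  mm <- default_mechanisms(axon = mechanism("passive"))
  res <- find_magnetic_threshold(fiber, standard_coil(), standard_pulse(),
                                 bounds = c(10, 100), cap = 1000,
                                 mech_map = mm,
                                 config = sim_config(t_stop = 2,
                                                     save_every = 10L))
  expect_true(res$unexcitable)
  expect_true(is.na(res$threshold))
})

test_that("suprathreshold stimulation of the long axon initiates at the
           activating-function maximum", {
  co <- standard_coil()
  ax <- build_straight_axon(100, 16e4)
  cfg <- sim_config(t_stop = 4, save_every = 5L)
  cmp <- compile_neuron(ax, config = cfg)
  af <- activating_function_profile(cmp, co)
  x_af <- with(cmp$comp, (x0 + x1) / 2)[which.max(af)]
  sim <- ms_run(cmp, co, standard_pulse(15000), config = cfg)
  ini <- initiation_site(sim)
  expect_true(ini$spike)
  x_init <- with(sim$comp, (x0 + x1) / 2)[ini$comp]
  expect_lt(abs(x_init - x_af), 2500)   # within a few compartments (um)
  expect_equal(abs(x_init) * 1e-4, locate_axon_hotspot(co) * 100,
               tolerance = 0.05)
})
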