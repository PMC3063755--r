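test_that("induced currents vanish for radial fibers and telescope along paths", {
  # a fiber through the coil axis projection runs radially: the azimuthal
  # field is everywhere perpendicular to it
  co <- coil(0.02, 30, 0.01)               # centered on the fiber
  fiber <- build_straight_axon(100, 2e4)
  i_rad <- induced_segment_currents(fiber, co)
  expect_lt(max(abs(i_rad)), 1e-18)
  # shifted fiber: per-compartment differences telescope to the end values
  co2 <- standard_coil()
  cmp <- compile_neuron(fiber)
  i_nA <- induced_segment_currents(cmp, co2)
  cp <- cmp$comp
  ends <- spatial_field(rbind(c(min(cp$x0), 0), c(max(cp$x1), 0)) * 1e-6, co2)
  r_a_SI <- 4 * (cmp$Ra / 100) / (pi * (cp$diam[1] * 1e-6)^2)
  expect_equal(sum(i_nA), unname(-(ends[2, 1] - ends[1, 1]) / r_a_SI * 1e9),
               tolerance = 1e-9)
})

test_that("induced drive scales linearly and reverses with pulse polarity", {
  co <- standard_coil()
  cell <- place(soma_cell(2), offset = c(-16000, 0))
  mm <- default_mechanisms(soma = mechanism("passive"))  # fully passive
  cfg <- sim_config(t_stop = 2, save_every = 5L)
  s1 <- ms_run(cell, co, standard_pulse(5000), mech_map = mm, config = cfg)
  s2 <- ms_run(cell, co, standard_pulse(10000), mech_map = mm, config = cfg)
  expect_equal(max(s2$v) - (-65), 2 * (max(s1$v) - (-65)), tolerance = 1e-6)
  # a negatively charged capacitor mirrors every deflection
  pneg <- standard_pulse(5000); pneg$V0 <- -5000
  s3 <- ms_run(cell, co, pneg, mech_map = mm, config = cfg)
  expect_equal(s3$v - (-65), -(s1$v - (-65)), tolerance = 1e-9)
})

test_that("passive cable steady state matches the analytic decay profile", {
  # semi-infinite-cable input resistance at the end of a long fiber
  cc <- cable_constants(2)
  fiber <- build_straight_axon(2, 6 * cc$lambda_um)
  mm <- default_mechanisms(axon = mechanism("passive"))
  rin <- input_resistance(fiber, site = c(1, 0), step_amplitude = -0.005,
                          mech_map = mm, settle = 10, dur = 300, dt = 0.05)
  r_inf <- sqrt(cc$r_m * cc$r_a) / 1e6    # MOhm
  expect_equal(rin, r_inf, tolerance = 0.02)
  # isolated passive soma: R = 1/(g * area)
  soma <- build_soma_dendrites(20, 1, 0)
  mp <- default_mechanisms(soma = mechanism("passive"))
  r_soma <- input_resistance(soma, site = c(1, 0.5), mech_map = mp,
                             settle = 10, dur = 200, dt = 0.05)
  area <- pi * (20e-4)^2
  expect_equal(r_soma, 1 / (mechanism("passive")$g_pas * area) / 1e6,
               tolerance = 0.01)
  # adding dendrites strictly decreases the somatic input resistance
  rins <- vapply(0:3, function(n)
    input_resistance(build_soma_dendrites(20, 1, n, 600), site = c(1, 0.5)),
    numeric(1))
  expect_true(all(diff(rins) < 0))
})

test_that("the tree solver agrees with a dense linear-algebra reference", {
  # small passive tree stepped by an independent dense backward-Euler solver
  cell <- build_bifurcation_cell(10, 3, theta = 40, stem_len = 100,
                                 branch_len = 80)
  mm <- default_mechanisms(soma = mechanism("passive"))
  cfg <- sim_config(dt = 0.01, t_stop = 1,
                    iclamp = list(list(section = 3, pos = 0.9, amp = 0.05,
                                       start = 0.2, dur = 0.5)))
  cmp <- compile_neuron(cell, mm, cfg)
  sim <- ms_run(cell, mech_map = mm, config = cfg)
  n <- nrow(cmp$comp)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- cmp$parent0[i] + 1L
    if (p > 0) {
      g <- cmp$g_parent_uS[i]
      G[i, i] <- G[i, i] + g; G[p, p] <- G[p, p] + g
      G[i, p] <- G[i, p] - g; G[p, i] <- G[p, i] - g
    }
  }
  nsteps <- round(cfg$t_stop / cfg$dt)
  v <- rep(-65, n)
  ic_comp <- which.min(abs(cmp$comp$pos - 0.9) +
                         (cmp$comp$section != 3) * 10)
  for (s in seq_len(nsteps)) {
    t_new <- s * cfg$dt
    A <- diag(cmp$cap_nF / cfg$dt + cmp$gl_uS, n) + G
    b <- cmp$cap_nF / cfg$dt * v + cmp$gl_uS * cmp$el
    if (t_new >= 0.2 && t_new < 0.7) b[ic_comp] <- b[ic_comp] + 0.05
    v <- solve(A, b)
  }
  expect_equal(as.numeric(sim$v[, ncol(sim$v)]), as.numeric(v),
               tolerance = 1e-10)
})

test_that("subthreshold polarization profile tracks the activating function", {
  co <- standard_coil()
  fiber <- build_straight_axon(4, 8e4)
  mm <- default_mechanisms(axon = mechanism("passive"))
  cfg <- sim_config(t_stop = 1.2, save_every = 10L)
  cmp <- compile_neuron(fiber, mm, cfg)
  af <- activating_function_profile(cmp, co, mm, cfg)
  sim <- ms_run(cmp, co, standard_pulse(1000), mech_map = mm, config = cfg)
  # peak deflection (signed by direction) per compartment
  defl <- apply(sim$v + 65, 1, function(tr) tr[which.max(abs(tr))])
  expect_gt(cor(defl, af), 0.99)
})

test_that("temporal and spatial discretization are converged", {
  co <- standard_coil()
  cell <- hotspot_cell(1)
  p <- standard_pulse(5e4)
  s1 <- ms_run(cell, co, p, config = sim_config(dt = 0.001, t_stop = 3,
                                                record = list(c(1, 0.5))))
  s2 <- ms_run(cell, co, p, config = sim_config(dt = 0.0005, t_stop = 3,
                                                record = list(c(1, 0.5))))
  expect_lt(abs(max(s1$v) - max(s2$v)), 0.1)
  # halving the compartment length cap leaves the magnetic threshold alone
  ax <- build_straight_axon(100, 16e4)
  th1 <- find_magnetic_threshold(ax, co, standard_pulse(), resolution = 16,
                                 config = sim_config(t_stop = 4, save_every = 5L))
  th2 <- find_magnetic_threshold(ax, co, standard_pulse(), resolution = 16,
                                 config = sim_config(t_stop = 4, save_every = 5L,
                                                     d_lambda = 0.05))
  expect_lt(abs(th1$threshold - th2$threshold) / th1$threshold, 0.01)
})

test_that("simulations error cleanly on non-planar neurons with a coil", {
  cell <- build_soma_dendrites(20, 1, 1, 300)
  cell$planar <- FALSE
  cell$sections[[2]]$points[2, 3] <- 50
  expect_error(ms_run(cell, standard_coil(), standard_pulse(100)), "planar")
})
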