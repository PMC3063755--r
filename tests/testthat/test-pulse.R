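test_that("damping classification follows the discriminant", {
  expect_equal(classify_mode(rlc_params(36, 0.09, 13e-6, 200e-6)),
               "underdamped")
  expect_equal(classify_mode(rlc_params(36, 1.1, 13e-6, 200e-6)),
               "overdamped")
  # critical resistance 2*sqrt(L/C) = 0.50990... Ohm; boundary -> overdamped
  Rc <- 2 * sqrt(13e-6 / 200e-6)
  expect_equal(Rc, 0.50990195, tolerance = 1e-7)
  expect_equal(classify_mode(rlc_params(36, Rc, 13e-6, 200e-6)), "overdamped")
  expect_equal(classify_mode(rlc_params(36, Rc * 0.999, 13e-6, 200e-6)),
               "underdamped")
})

test_that("waveform initial conditions and linearity hold in both regimes", {
  for (R in c(0.09, 1.1)) {
    p <- rlc_params(36, R, 13e-6, 200e-6)
    w0 <- waveform(0, p)
    expect_equal(w0$I, 0)
    expect_equal(w0$dIdt, p$V0 / p$L)
    t <- seq(0, 1e-3, by = 1e-5)
    p2 <- p; p2$V0 <- 72
    expect_equal(waveform(t, p2)$I, 2 * waveform(t, p)$I)
    expect_equal(waveform(t, p2)$dIdt, 2 * waveform(t, p)$dIdt)
  }
})

test_that("closed-form discharge matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  t <- seq(0, 1.5e-3, by = 5e-6)
  for (R in c(0.09, 1.1)) {
    p <- rlc_params(36, R, 13e-6, 200e-6)
    num <- oracle_rlc(p, t)
    ana <- waveform(t, p)$I
    expect_lt(max(abs(ana - num$I)) / max(abs(num$I)), 1e-6)
  }
})

test_that("dI/dt is the derivative of I and energy is conserved", {
  p <- rlc_params(36, 0.09, 13e-6, 200e-6)
  dt <- 1e-7
  t <- seq(dt, 1e-3, by = 1e-5)
  w <- waveform(t, p)
  wp <- waveform(t + dt, p)
  wm <- waveform(t - dt, p)
  expect_lt(max(abs((wp$I - wm$I) / (2 * dt) - w$dIdt)) / max(abs(w$dIdt)),
            1e-5)
  # dissipated + stored energy accounts for the initial (1/2) C V0^2
  tt <- seq(0, 0.2, by = 1e-6)   # long after the pulse has rung down
  I <- waveform(tt, p)$I
  dissipated <- sum(I^2 * p$R) * 1e-6
  expect_equal(dissipated, 0.5 * p$C * p$V0^2, tolerance = 1e-4)
})

test_that("device energy is the initial capacitor energy", {
  expect_equal(device_energy(rlc_params(0, 0.09, 13e-6, 200e-6)), 0)
  e1 <- device_energy(rlc_params(18, 0.09, 13e-6, 200e-6))
  e2 <- device_energy(rlc_params(36, 0.09, 13e-6, 200e-6))
  expect_equal(e2, 4 * e1)
  expect_equal(e2, 0.1296)
})

test_that("effective duration is monotone in C and follows sqrt scaling", {
  dur <- vapply(c(50, 100, 200, 400, 700) * 1e-6, function(C)
    effective_duration(rlc_params(36, 0.09, 13e-6, C)), numeric(1))
  expect_true(all(diff(dur) > 0))
  # near-lossless limit: period scales as sqrt(C) and sqrt(L)
  p <- rlc_params(36, 1e-4, 13e-6, 200e-6)
  p4C <- rlc_params(36, 1e-4, 13e-6, 800e-6)
  expect_equal(effective_duration(p4C) / effective_duration(p), 2,
               tolerance = 1e-4)
  p2L <- rlc_params(36, 1e-4, 26e-6, 200e-6)
  expect_equal(effective_duration(p2L) / effective_duration(p), sqrt(2),
               tolerance = 1e-4)
  # overdamped branch returns a finite decay-based duration
  po <- rlc_params(36, 1.1, 13e-6, 200e-6)
  expect_gt(effective_duration(po), 0)
})

test_that("unit-suffixed parameters parse into SI", {
  p <- rlc_params("36V", "0.09Ohm", "13uH", "200uF")
  expect_equal(p$L, 1.3e-5)
  expect_equal(p$C, 2e-4)
  expect_equal(parse_quantity("2cm"), 0.02)
  expect_equal(parse_quantity(c("5mm", "1.5kOhm")), c(5e-3, 1500))
  expect_error(parse_quantity("12parsec"), "unknown")
})
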