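test_that("loop vector potential has the required symmetries and limits", {
  expect_equal(vector_potential_per_turn(0, 0.01, 0.02), 0)
  rho <- c(0.005, 0.013, 0.021, 0.05)
  expect_equal(vector_potential_per_turn(rho, 0.014, 0.02),
               vector_potential_per_turn(rho, -0.014, 0.02))
  # decays toward zero far from the loop
  expect_lt(vector_potential_per_turn(5, 0.01, 0.02),
            vector_potential_per_turn(0.02, 0.01, 0.02) * 1e-3)
  expect_error(vector_potential_per_turn(0.02, 0, 0.02), "singular")
})

test_that("closed form matches the Biot-Savart line-integral oracle", {
  # a reference point, high-resolution oracle
  a <- vector_potential_per_turn(0.016, 0.01, 0.02)
  expect_equal(a, oracle_loop_A(0.016, 0.01, 0.02, n = 1e5),
               tolerance = 1e-6)
  # random field points away from the wire annulus
  set.seed(42)
  for (i in 1:100) {
    rho <- runif(1, 0.001, 0.06)
    z <- runif(1, 0.002, 0.05)
    if (rho > 0.9 * 0.02 && rho < 1.1 * 0.02 && z < 0.002) next
    expect_equal(vector_potential_per_turn(rho, z, 0.02),
                 oracle_loop_A(rho, z, 0.02), tolerance = 1e-5)
  }
})

test_that("line_integral_field agrees with the closed form and superposes", {
  path <- circular_path(0.02, n = 2000)
  A <- line_integral_field(path, c(0.016, 0, 0.01), n_elements = 1e5)
  # at (rho, 0, z) the azimuthal direction is +y
  expect_equal(A[2], vector_potential_per_turn(0.016, 0.01, 0.02),
               tolerance = 1e-6)
  # on the loop axis the potential vanishes by symmetry
  A0 <- line_integral_field(path, c(0, 0, 0.01), n_elements = 2e4)
  expect_lt(max(abs(A0)), 1e-18)
  # figure-of-eight: one closed path of two opposed tangent loops equals the
  # sum of the individual loop potentials
  rot_start <- function(p, k) rbind(p[k:(nrow(p) - 1), ], p[1:k, ])
  n <- 2000
  # both loops pass through the origin; start each there so the joined
  # figure-of-eight is a single closed polyline
  p1 <- circular_path(0.02, n, center = c(-0.02, 0, 0))
  p2 <- rot_start(circular_path(0.02, n, center = c(0.02, 0, 0),
                                sense = -1), n / 2 + 1)
  p8 <- rbind(p1, p2[-1, ])
  pt <- c(0.005, 0.007, 0.01)
  expect_equal(line_integral_field(p8, pt, 4e4),
               line_integral_field(p1, pt, 2e4) +
                 line_integral_field(p2, pt, 2e4), tolerance = 1e-6)
  expect_error(line_integral_field(path[1:100, ], pt), "open path")
  expect_error(line_integral_field(path, c(0.02, 0, 0)), "singular")
})

test_that("spatial field is tangential, radially symmetric, and scales", {
  co <- coil(0.02, turns = 30, standoff = 0.01)
  set.seed(7)
  pts <- cbind(runif(1000, -0.05, 0.05), runif(1000, -0.05, 0.05))
  S <- spatial_field(pts, co)
  dot <- S[, 1] * pts[, 1] + S[, 2] * pts[, 2]
  mag <- sqrt(rowSums(S^2))
  expect_lt(max(abs(dot) / pmax(mag * sqrt(rowSums(pts^2)), 1e-300)), 1e-10)
  # |S| depends only on the radial distance
  d <- 0.017
  on_x <- spatial_field(c(d, 0), co)
  on_y <- spatial_field(c(0, d), co)
  expect_equal(sqrt(sum(on_x^2)), sqrt(sum(on_y^2)), tolerance = 1e-10)
  # on the +x axis the field is purely azimuthal (along y)
  off <- coil(0.02, 30, 0.01, center_offset = c(0.003, -0.004))
  S1 <- spatial_field(c(off$center_offset[1] + 0.01, off$center_offset[2]), off)
  expect_equal(S1[1], 0, tolerance = 1e-300)
  expect_gt(abs(S1[2]), 0)
  # linear in turns; doubling mu doubles |S|
  co60 <- coil(0.02, 60, 0.01)
  expect_equal(spatial_field(pts[1:10, ], co60),
               2 * spatial_field(pts[1:10, ], co))
  co2mu <- coil(0.02, 30, 0.01, mu = 8e-7 * pi)
  expect_equal(spatial_field(pts[1:10, ], co2mu),
               2 * spatial_field(pts[1:10, ], co))
  # zero at the coil axis
  expect_equal(as.numeric(spatial_field(c(0, 0), co)), c(0, 0))
})

test_that("radial field maximum sits inside the coil radius at 1 cm standoff", {
  co <- coil(0.02, 30, 0.01)
  rmax <- locate_radial_maximum(co, scan_resolution = 1e-4)
  expect_lt(rmax, co$radius)
  expect_equal(rmax, 0.0198, tolerance = 0.01)
  # invariant to the number of turns (a uniform scale factor)
  expect_equal(rmax, locate_radial_maximum(coil(0.02, 5, 0.01), 1e-4))
  # the maximum moves outward with standoff (dipole limit rho = z/sqrt(2))
  standoffs <- c(0.005, 0.01, 0.02, 0.04)
  rm <- vapply(standoffs, function(z)
    locate_radial_maximum(coil(0.02, 30, z), 2e-4), numeric(1))
  expect_true(all(diff(rm) > 0))
})

test_that("activating hotspot of the one-radius-shifted fiber is ~1.6 cm out", {
  co <- standard_coil()
  x <- locate_axon_hotspot(co, scan_resolution = 1e-4)
  expect_equal(x, 0.0166, tolerance = 0.01)
  expect_lt(x, co$radius)
})

test_that("field grids equal analytic evaluation and translate with the coil", {
  co <- coil(0.02, 30, 0.01)
  g <- export_field_grid(co, extent = 0.002, resolution = 2e-4,
                         center = c(0.0198, 0))
  i <- 4; j <- 9
  S <- spatial_field(c(g$x[i], g$y[j]), co)
  expect_equal(g$Sx[i, j], S[1])
  expect_equal(g$Sy[i, j], S[2])
  # translation equivariance
  co_off <- coil(0.02, 30, 0.01, center_offset = c(0.003, -0.002))
  g2 <- export_field_grid(co_off, extent = 0.002, resolution = 2e-4,
                          center = c(0.0198 + 0.003, -0.002))
  expect_equal(g2$Sx, g$Sx, tolerance = 1e-12)
  expect_equal(g2$Sy, g$Sy, tolerance = 1e-12)
  # downsampling a fine grid equals direct coarse sampling
  gf <- export_field_grid(co, extent = 0.001, resolution = 1e-4)
  gc <- export_field_grid(co, extent = 0.001, resolution = 2e-4)
  expect_equal(gf$Sx[seq(1, length(gf$x), 2), seq(1, length(gf$y), 2)], gc$Sx)
  expect_error(export_field_grid(co, extent = 0.04, resolution = 1e-6),
               "max_cells")
  # text export round trip
  d <- tempfile(); dir.create(d)
  paths <- write_field_grid(g, d, "f")
  expect_true(all(file.exists(paths)))
  back <- as.matrix(read.table(paths[1], sep = "\t"))
  expect_equal(unname(back), unname(g$Sx), tolerance = 1e-12)
})
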