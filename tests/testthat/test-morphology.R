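test_that("Rall 3/2-power law gives the printed daughter diameters", {
  expect_equal(round(rall_daughter_diameter(5, 2), 4), 3.1498)
  expect_equal(rall_daughter_diameter(7.3, 1), 7.3)
  expect_equal(rall_daughter_diameter(20, 2), 12.599210, tolerance = 1e-6)
  # conservation of d^(3/2) across the branch point
  for (n in 1:4) {
    d <- rall_daughter_diameter(5, n)
    expect_equal(n * d^1.5, 5^1.5, tolerance = 1e-6)
  }
})

test_that("toy builders produce the stated geometries", {
  ax <- build_straight_axon(100, "16cm")
  expect_equal(total_length(ax), 16e4)
  expect_equal(ax$sections[[1]]$diam, 100)
  # zero-angle bend is geometrically the unbent cell
  b0 <- build_bent_dendrite_cell(20, 5, theta = 0)
  straight <- build_diameter_step_cell(20, 5, ratio = 1)
  pts_b <- do.call(rbind, lapply(b0$sections, `[[`, "points"))
  pts_s <- do.call(rbind, lapply(straight$sections, `[[`, "points"))
  expect_equal(sort(unique(pts_b[, 1])), sort(unique(pts_s[, 1])))
  expect_equal(total_length(b0), total_length(straight))
  # Rall daughters in the bifurcation cell
  bif <- build_bifurcation_cell(20, 5, theta = 60, rall = TRUE)
  expect_equal(bif$sections[[3]]$diam, 3.1498, tolerance = 1e-4)
  expect_equal(bif$sections[[4]]$diam, bif$sections[[3]]$diam)
  # dendrites at equal angular spacing
  cell <- build_soma_dendrites(20, 1, 4, 600)
  tips <- t(vapply(cell$sections[-1], function(s) s$points[2, 1:2],
                   numeric(2)))
  ang <- sort(atan2(tips[, 2], tips[, 1]))
  expect_equal(diff(ang), rep(pi / 2, 3), tolerance = 1e-9)
  # myelinated axon alternates internode and node sections
  my <- build_soma_myelinated_axon(n_internodes = 3)
  expect_equal(vapply(my$sections, `[[`, "", "tag"),
               c("soma", rep(c("myelin", "node"), 3)))
  expect_equal(total_length(my), 20 + 3 * 101)
  # invalid descriptors
  expect_error(build_bent_dendrite_cell(20, 5, theta = 200), "theta")
  expect_error(build_straight_axon(0, 1000))
  expect_error(build_toy(list(kind = "spiral")), "unknown")
  expect_equal(total_length(build_toy(list(kind = "straight_axon",
                                           diam = 50, length = 1000))), 1000)
})

test_that("place is a rigid transform and matches an opposite coil shift", {
  cell <- build_bifurcation_cell(20, 5, theta = 45)
  moved <- place(cell, offset = c(120.5, -34), rotation = 33)
  expect_equal(total_length(moved), total_length(cell))
  expect_equal(membrane_area(moved), membrane_area(cell))
  # inverse transform restores coordinates (undo translation then rotation)
  undone <- place(place(moved, offset = c(-120.5, 34)), rotation = -33)
  p0 <- do.call(rbind, lapply(cell$sections, `[[`, "points"))
  p1 <- do.call(rbind, lapply(undone$sections, `[[`, "points"))
  expect_equal(p1, p0, tolerance = 1e-9)
  check_neuron(moved)
  # shifting the neuron by (a, b) = shifting the coil center by (-a, -b)
  co <- standard_coil()
  co2 <- coil(co$radius, co$turns, co$standoff,
              center_offset = co$center_offset - c(250e-6, -100e-6))
  i1 <- induced_segment_currents(place(cell, offset = c(250, -100)), co)
  i2 <- induced_segment_currents(cell, co2)
  expect_equal(i1, i2, tolerance = 1e-9)
})

test_that("tree integrity violations are caught", {
  cell <- build_soma_dendrites(20, 1, 2, 300)
  broken <- cell
  broken$sections[[2]]$parent <- 5L
  expect_error(check_neuron(broken), "parent")
  broken2 <- cell
  broken2$sections[[3]]$points[, 3] <- 10
  expect_error(check_neuron(broken2), "planar")
})
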