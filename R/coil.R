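#' Define a circular stimulation coil
#'
#' Geometry of a planar multi-turn circular coil lying in the plane
#' `z = standoff`, with its center projected onto the neuron plane (`z = 0`)
#' at `center_offset`. All lengths in meters (SI); the simulator performs a
#' single explicit conversion when coupling to morphologies in micrometers.
#'
#' @param radius coil radius in m (e.g. `0.02` or `"2cm"`).
#' @param turns number of loops (N >= 1).
#' @param standoff plane-to-plane distance between coil and neuron plane, m.
#' @param center_offset length-2 vector: coil center in neuron-plane
#'   coordinates (m).
#' @param mu magnetic permeability, H/m. Default free-space `4*pi*1e-7`.
#' @return an object of class `ms_coil`.
#' @examples
#' co <- coil("2cm", turns = 30, standoff = "1cm")
#' @export
coil <- function(radius, turns = 30L, standoff, center_offset = c(0, 0),
                 mu = 4e-7 * pi) {
  radius <- parse_quantity(radius)
  standoff <- parse_quantity(standoff)
  center_offset <- parse_quantity(center_offset)
  stopifnot(radius > 0, turns >= 1, standoff > 0, mu > 0,
            length(center_offset) == 2)
  structure(list(radius = radius, turns = as.integer(turns),
                 standoff = standoff, center_offset = as.numeric(center_offset),
                 mu = mu),
            class = "ms_coil")
}

#' @export
print.ms_coil <- function(x, ...) {
  cat(sprintf("<ms_coil> r = %.3g cm, %d turns, standoff %.3g cm, center (%.3g, %.3g) cm\n",
              x$radius * 100, x$turns, x$standoff * 100,
              x$center_offset[1] * 100, x$center_offset[2] * 100))
  invisible(x)
}

#' Azimuthal vector potential of a single circular loop per unit current
#'
#' Closed-form magnetic vector potential A_phi of a circular loop of radius
#' `coil_radius` carrying unit current, evaluated at radial distance `rho`
#' from the loop axis and axial distance `z` from the loop plane. Uses the
#' complete elliptic integrals K(m) and E(m) in the *parameter* convention
#' `m = k^2 = 4 r rho / ((r + rho)^2 + z^2)` (the convention taken by
#' `pracma::ellipke`); the choice is pinned by the line-integral oracle in
#' the test suite.
#'
#' @param rho radial distance(s) from the loop axis, m (>= 0).
#' @param z axial distance(s) from the loop plane, m.
#' @param coil_radius loop radius, m.
#' @param mu permeability, H/m.
#' @return A_phi in T*m per ampere (equivalently V*s/m per A); zero on the
#'   axis, finite everywhere off the wire.
#' @export
vector_potential_per_turn <- function(rho, z, coil_radius, mu = 4e-7 * pi) {
  stopifnot(all(rho >= 0), coil_radius > 0)
  n <- max(length(rho), length(z))
  rho <- rep_len(rho, n); z <- rep_len(z, n)
  if (any(rho == coil_radius & z == 0))
    stop("singular input: evaluation point lies on the coil wire", call. = FALSE)
  out <- numeric(n)
  off <- rho > 0
  if (any(off)) {
    r <- coil_radius
    D2 <- (r + rho[off])^2 + z[off]^2
    m <- 4 * r * rho[off] / D2
    ke <- pracma::ellipke(m)
    out[off] <- (mu / (4 * pi)) * (4 * r / sqrt(D2)) *
      ((2 - m) * ke$k - 2 * ke$e) / m
  }
  out
}

#' Spatial factor of the induced electric field of a coil
#'
#' The induced field separates as `E(x, y, t) = S(x, y) * g(t)` with the
#' temporal factor `g(t) = dI/dt` of the coil current. This returns the
#' spatial factor `S = -N * A_phi(rho, standoff) * phi_hat` at points of the
#' neuron plane, decomposed into Cartesian components via the azimuthal unit
#' vector `phi_hat = (-(y - cy)/rho, (x - cx)/rho)`. At `rho = 0` the field
#' is zero by symmetry.
#'
#' @param point numeric length-2 vector or n-by-2 matrix of (x, y) in m.
#' @param coil an [coil()] object.
#' @return n-by-2 matrix with columns Sx, Sy, in (V/m) per (A/s).
#' @export
spatial_field <- function(point, coil) {
  stopifnot(inherits(coil, "ms_coil"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  dx <- p[, 1] - coil$center_offset[1]
  dy <- p[, 2] - coil$center_offset[2]
  rho <- sqrt(dx^2 + dy^2)
  A <- vector_potential_per_turn(rho, coil$standoff, coil$radius, coil$mu)
  S <- cbind(Sx = numeric(nrow(p)), Sy = numeric(nrow(p)))
  off <- rho > 0
  # E = -N dA/dt => S = -N A(rho) phi_hat per unit dI/dt
  S[off, 1] <- -coil$turns * A[off] * (-dy[off] / rho[off])
  S[off, 2] <- -coil$turns * A[off] * ( dx[off] / rho[off])
  S
}

#' Vector potential of an arbitrary closed coil path by line integral
#'
#' Numeric quadrature of the Biot-Savart-type current-element sum for the
#' magnetic vector potential, `A = (mu/4pi) * sum(dl / R)`, per unit
#' current and single turn. Serves both as the independent oracle for the
#' closed-form loop potential and as the generic-coil pathway (e.g. a
#' figure-of-eight path built from two opposed loops).
#'
#' @param path k-by-3 matrix of points (m) forming a closed polyline: the
#'   last point must equal the first.
#' @param point length-3 evaluation point (m).
#' @param n_elements number of straight elements the path is resampled into
#'   (>= 3); elements are distributed along the polyline by arc length.
#' @param mu permeability, H/m.
#' @return length-3 vector potential (T*m/A).
#' @export
line_integral_field <- function(path, point, n_elements = 1e4, mu = 4e-7 * pi) {
  stopifnot(is.matrix(path), ncol(path) == 3, n_elements >= 3)
  if (max(abs(path[1, ] - path[nrow(path), ])) > 1e-12)
    stop("open path: first and last points of the coil polyline must coincide",
         call. = FALSE)
  # resample the polyline at n_elements midpoints
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s_mid <- (seq_len(n_elements) - 0.5) / n_elements * total
  ds <- total / n_elements
  idx <- findInterval(s_mid, cum, rightmost.closed = TRUE)
  frac <- (s_mid - cum[idx]) / len[idx]
  pts <- path[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  dl <- seg[idx, , drop = FALSE] / len[idx] * ds
  R <- sqrt((point[1] - pts[, 1])^2 + (point[2] - pts[, 2])^2 +
            (point[3] - pts[, 3])^2)
  if (min(R) < ds)
    stop("singular input: evaluation point lies on the coil path", call. = FALSE)
  (mu / (4 * pi)) * colSums(dl / R)
}

#' Circular coil path for use with [line_integral_field()]
#' @param radius loop radius (m); @param n number of polyline points;
#' @param center length-3 center; @param sense +1 counterclockwise, -1 clockwise.
#' @return (n+1)-by-3 closed polyline matrix.
#' @export
circular_path <- function(radius, n = 360, center = c(0, 0, 0), sense = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1) * sense
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3])
}

#' Radial location of the maximal induced-field magnitude
#'
#' Scans the radial profile of `|S(rho)|` on the neuron plane and returns the
#' argmax, to within `scan_resolution`. Note that for a one-radius-shifted
#' straight fiber the biologically operative location is not this maximum but
#' the maximum of the field *gradient* along the fiber; see
#' [locate_axon_hotspot()].
#'
#' @param coil an [coil()] object.
#' @param scan_resolution radial step of the scan, m.
#' @param rho_max outer limit of the scan, m (default 3 coil radii).
#' @return radial distance (m) of max |S| from the coil axis.
#' @export
locate_radial_maximum <- function(coil, scan_resolution = 1e-4,
                                  rho_max = 3 * coil$radius) {
  stopifnot(inherits(coil, "ms_coil"), scan_resolution > 0)
  rho <- seq(scan_resolution, rho_max, by = scan_resolution)
  A <- vector_potential_per_turn(rho, coil$standoff, coil$radius, coil$mu)
  rho[which.max(A)]
}

#' Along-fiber location of the maximal activating drive for a shifted axon
#'
#' For a straight fiber parallel to the x-axis at perpendicular distance
#' `line_offset` from the coil axis (default one coil radius, the
#' lowest-threshold configuration), computes the x-position at which the
#' magnitude of the along-fiber field gradient `|dE_x/dx|` is maximal. This
#' is the activating-function hotspot where a suprathreshold pulse initiates
#' the action potential; for a 2 cm coil 1 cm above the fiber it lies about
#' 1.6 cm from the coil center's x-position, inside the coil radius.
#'
#' @param coil an [coil()] object.
#' @param line_offset perpendicular distance of the fiber from the coil
#'   center, m. Default one coil radius.
#' @param scan_resolution step of the x-scan, m.
#' @param x_max scan limit, m.
#' @return |x| (m) of the maximal along-fiber gradient, relative to the coil
#'   center (the two hotspots at +/- x are symmetric).
#' @export
locate_axon_hotspot <- function(coil, line_offset = coil$radius,
                                scan_resolution = 1e-4,
                                x_max = 3 * coil$radius) {
  stopifnot(inherits(coil, "ms_coil"), scan_resolution > 0)
  x <- seq(-x_max, x_max, by = scan_resolution)
  pts <- cbind(coil$center_offset[1] + x,
               coil$center_offset[2] - line_offset)
  Sx <- spatial_field(pts, coil)[, 1]
  g <- diff(Sx) / scan_resolution
  xm <- x[-1] - scan_resolution / 2
  abs(xm[which.max(abs(g))])
}

#' Sample the spatial field on a regular grid
#'
#' Evaluates the analytic spatial factor at cell centers of a square grid of
#' half-width `extent` around the grid center. The engine itself always
#' evaluates the field analytically at segment endpoints; grids are an
#' export/visualization feature.
#'
#' @param coil an [coil()] object.
#' @param extent half-width of the square grid, m.
#' @param resolution grid spacing, m.
#' @param center length-2 grid center in neuron-plane coordinates, m.
#' @param max_cells memory cap on the number of grid cells.
#' @return an `ms_field_grid`: list with `x`, `y` (cell-center coordinates),
#'   `Sx`, `Sy` (matrices, x indexing rows), and coil/grid metadata. Units of
#'   Sx, Sy: (V/m) per (A/s).
#' @export
export_field_grid <- function(coil, extent, resolution, center = c(0, 0),
                              max_cells = 4e7) {
  stopifnot(inherits(coil, "ms_coil"), extent > 0, resolution > 0)
  x <- seq(center[1] - extent, center[1] + extent, by = resolution)
  y <- seq(center[2] - extent, center[2] + extent, by = resolution)
  if (as.numeric(length(x)) * length(y) > max_cells)
    stop("grid of ", length(x), "x", length(y),
         " cells exceeds max_cells; evaluate the field analytically instead",
         call. = FALSE)
  pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  S <- spatial_field(pts, coil)
  structure(list(x = x, y = y,
                 Sx = matrix(S[, 1], nrow = length(x)),
                 Sy = matrix(S[, 2], nrow = length(x)),
                 extent = extent, resolution = resolution, center = center,
                 coil = coil, units = "V/m per (A/s)"),
            class = "ms_field_grid")
}

#' Write a sampled field grid as paired delimited-text matrices
#'
#' Writes `<prefix>_Sx.tsv`, `<prefix>_Sy.tsv` and a `<prefix>_meta.yaml`
#' sidecar holding extent, resolution, coil parameters and units.
#'
#' @param grid an `ms_field_grid` from [export_field_grid()].
#' @param dir output directory; @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_field_grid <- function(grid, dir = ".", prefix = "field") {
  stopifnot(inherits(grid, "ms_field_grid"))
  paths <- file.path(dir, paste0(prefix, c("_Sx.tsv", "_Sy.tsv", "_meta.yaml")))
  write.table(grid$Sx, paths[1], sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(grid$Sy, paths[2], sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(extent_m = grid$extent, resolution_m = grid$resolution,
               center_m = as.numeric(grid$center),
               coil = list(radius_m = grid$coil$radius, turns = grid$coil$turns,
                           standoff_m = grid$coil$standoff,
                           center_offset_m = as.numeric(grid$coil$center_offset),
                           mu_H_per_m = grid$coil$mu),
               units = grid$units)
  yaml::write_yaml(meta, paths[3])
  invisible(paths)
}
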