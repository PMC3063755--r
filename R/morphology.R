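# Neuron morphology: trees of cylindrical sections with 3-D coordinates.
#
# Coordinates are micrometers. A section is an unbranched polyline with a
# single diameter and a mechanism tag; sections form a tree (parent index 0
# marks the root). `parent_pos` in [0, 1] is the normalized position along
# the parent at which a child attaches (1 = distal end, 0.5 = midpoint, used
# for dendrites radiating from a soma).

as_um <- function(x) {
  if (is.character(x)) parse_quantity(x) * 1e6 else x
}

new_section <- function(points, diam, tag, parent = 0L, parent_pos = 1) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(nrow(points) >= 2, diam > 0)
  seglen <- sqrt(rowSums(diff(points)^2))
  if (any(seglen <= 0)) stop("section has a zero-length segment", call. = FALSE)
  list(points = points, diam = diam, tag = tag,
       parent = as.integer(parent), parent_pos = parent_pos)
}

new_neuron <- function(sections, Ra = HH_CONST$Ra, planar = TRUE) {
  n <- structure(list(sections = sections, Ra = Ra, planar = planar),
                 class = "ms_neuron")
  check_neuron(n)
  n
}

#' Validate tree integrity of a neuron
#'
#' Checks: every non-root section has a parent with smaller index (which
#' rules out cycles), positive diameters and segment lengths, and, if the
#' neuron is flagged planar, that all z coordinates are 0.
#'
#' @param neuron an `ms_neuron`.
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
check_neuron <- function(neuron) {
  stopifnot(inherits(neuron, "ms_neuron"))
  secs <- neuron$sections
  roots <- 0L
  for (i in seq_along(secs)) {
    s <- secs[[i]]
    if (s$parent == 0L) roots <- roots + 1L
    else if (s$parent >= i || s$parent < 0L)
      stop("section ", i, ": parent must precede it in the tree", call. = FALSE)
    if (s$diam <= 0) stop("section ", i, ": non-positive diameter", call. = FALSE)
    if (any(sqrt(rowSums(diff(s$points)^2)) <= 0))
      stop("section ", i, ": zero-length segment", call. = FALSE)
    if (neuron$planar && any(abs(s$points[, 3]) > 1e-9))
      stop("section ", i, ": non-zero z in a planar neuron", call. = FALSE)
  }
  if (roots != 1L) stop("neuron must have exactly one root section", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ms_neuron <- function(x, ...) {
  cat(sprintf("<ms_neuron> %d sections, total length %.4g um, area %.4g um^2%s\n",
              length(x$sections), total_length(x), membrane_area(x),
              if (x$planar) ", planar" else ""))
  invisible(x)
}

#' Total path length of a neuron (um)
#' @param neuron an `ms_neuron`.
#' @export
total_length <- function(neuron) {
  sum(vapply(neuron$sections,
             function(s) sum(sqrt(rowSums(diff(s$points)^2))), numeric(1)))
}

#' Total membrane area of a neuron (um^2), cylinder lateral surfaces
#' @param neuron an `ms_neuron`.
#' @export
membrane_area <- function(neuron) {
  sum(vapply(neuron$sections, function(s)
    pi * s$diam * sum(sqrt(rowSums(diff(s$points)^2))), numeric(1)))
}

#' Rall daughter diameter from the 3/2-power branching law
#'
#' Impedance-matching branching: `n * d^(3/2) = parent_d^(3/2)`, hence
#' `d = parent_d / n^(2/3)`. A 5 um parent splitting into two equal
#' daughters gives 3.1498 um.
#'
#' @param parent_d parent diameter (um); @param n_daughters number of equal
#'   daughter branches (>= 1).
#' @return daughter diameter, um.
#' @export
rall_daughter_diameter <- function(parent_d, n_daughters) {
  stopifnot(parent_d > 0, n_daughters >= 1)
  parent_d / n_daughters^(2 / 3)
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

soma_section <- function(soma_d, center = c(0, 0, 0)) {
  # area-equivalent convention: cylinder with length = diameter (same lateral
  # area, pi d^2, as the sphere's surface)
  new_section(rbind(center - c(soma_d / 2, 0, 0), center + c(soma_d / 2, 0, 0)),
              diam = soma_d, tag = "soma", parent = 0L)
}

#' Toy-geometry builders
#'
#' Construct the planar artificial neurons used in the stimulation
#' experiments. All lengths and diameters in micrometers (strings with SI
#' suffixes, e.g. `"16cm"`, are converted). Mechanism tags: `soma` and
#' `node` carry Hodgkin-Huxley membrane, `axon` is Hodgkin-Huxley, `dend`
#' is passive, `myelin` is a purely capacitive insulating sheath
#' (see [default_mechanisms()]).
#'
#' * `build_straight_axon()`: a uniform axon along the x-axis centered at
#'   the origin.
#' * `build_soma_dendrites()`: a soma (cylinder with length = diameter) with
#'   `n` passive dendrites radiating at equal angles in the plane.
#' * `build_bent_dendrite_cell()`: soma plus a dendrite with a bend of
#'   `theta` degrees (angle between the second arm and the continuation of
#'   the first) partway along its length.
#' * `build_bifurcation_cell()`: soma plus a stem dendrite splitting into
#'   two daughters separated by `theta` degrees; `rall = TRUE` sets daughter
#'   diameters by [rall_daughter_diameter()].
#' * `build_diameter_step_cell()`: soma plus a dendrite whose diameter steps
#'   from `dend_d` to `dend_d / ratio` at its midpoint (`ratio` = first to
#'   second diameter).
#' * `build_soma_myelinated_axon()`: soma plus an axon of alternating
#'   myelinated internodes and nodes of Ranvier along +x.
#'
#' @param diam,length axon diameter and length (um).
#' @param soma_d soma diameter (um).
#' @param dend_d dendrite diameter (um).
#' @param n number of dendrites.
#' @param dend_len,seg1_len,seg2_len,stem_len,branch_len,seg_len dendrite
#'   arm lengths (um).
#' @param theta angle in degrees, within 0-180.
#' @param rall logical; use the 3/2-power law for daughter diameters.
#' @param ratio first-to-second diameter ratio of the step cell.
#' @param internode_d,node_d,internode_len,node_len,n_internodes myelinated
#'   axon geometry.
#' @param Ra axial resistivity, Ohm*cm.
#' @return an `ms_neuron`.
#' @name toy_builders
NULL

#' @rdname toy_builders
#' @export
build_straight_axon <- function(diam = 100, length = 16e4, Ra = HH_CONST$Ra) {
  diam <- as_um(diam); length <- as_um(length)
  stopifnot(diam > 0, length > 0)
  ax <- new_section(rbind(c(-length / 2, 0, 0), c(length / 2, 0, 0)),
                    diam = diam, tag = "axon", parent = 0L)
  new_neuron(list(ax), Ra = Ra)
}

#' @rdname toy_builders
#' @export
build_soma_dendrites <- function(soma_d = 20, dend_d = 1, n = 1,
                                 dend_len = 600, Ra = HH_CONST$Ra) {
  soma_d <- as_um(soma_d); dend_d <- as_um(dend_d); dend_len <- as_um(dend_len)
  stopifnot(soma_d > 0, dend_d > 0, n >= 0, dend_len > 0)
  secs <- list(soma_section(soma_d))
  if (n > 0) {
    ang <- (seq_len(n) - 1) / n * 360
    for (a in ang) {
      d <- c(cos(a * pi / 180), sin(a * pi / 180), 0)
      secs[[length(secs) + 1L]] <-
        new_section(rbind(c(0, 0, 0), dend_len * d), diam = dend_d,
                    tag = "dend", parent = 1L, parent_pos = 0.5)
    }
  }
  new_neuron(secs, Ra = Ra)
}

check_theta <- function(theta) {
  if (theta < 0 || theta > 180)
    stop("theta must lie in [0, 180] degrees", call. = FALSE)
  theta
}

#' @rdname toy_builders
#' @export
build_bent_dendrite_cell <- function(soma_d = 20, dend_d = 5, theta = 0,
                                     seg1_len = 300, seg2_len = 300,
                                     Ra = HH_CONST$Ra) {
  check_theta(theta)
  soma_d <- as_um(soma_d); dend_d <- as_um(dend_d)
  seg1_len <- as_um(seg1_len); seg2_len <- as_um(seg2_len)
  p0 <- c(soma_d / 2, 0, 0)
  p1 <- p0 + c(seg1_len, 0, 0)
  dir2 <- c(rot2(theta) %*% c(1, 0), 0)
  p2 <- p1 + seg2_len * dir2
  secs <- list(soma_section(soma_d),
               new_section(rbind(p0, p1, p2), diam = dend_d, tag = "dend",
                           parent = 1L, parent_pos = 1))
  new_neuron(secs, Ra = Ra)
}

#' @rdname toy_builders
#' @export
build_bifurcation_cell <- function(soma_d = 20, dend_d = 5, theta = 60,
                                   rall = TRUE, stem_len = 300,
                                   branch_len = 300, Ra = HH_CONST$Ra) {
  check_theta(theta)
  soma_d <- as_um(soma_d); dend_d <- as_um(dend_d)
  stem_len <- as_um(stem_len); branch_len <- as_um(branch_len)
  daughter_d <- if (rall) rall_daughter_diameter(dend_d, 2) else dend_d
  p0 <- c(soma_d / 2, 0, 0)
  p1 <- p0 + c(stem_len, 0, 0)
  d_up <- c(rot2(theta / 2) %*% c(1, 0), 0)
  d_dn <- c(rot2(-theta / 2) %*% c(1, 0), 0)
  secs <- list(
    soma_section(soma_d),
    new_section(rbind(p0, p1), diam = dend_d, tag = "dend", parent = 1L),
    new_section(rbind(p1, p1 + branch_len * d_up), diam = daughter_d,
                tag = "dend", parent = 2L),
    new_section(rbind(p1, p1 + branch_len * d_dn), diam = daughter_d,
                tag = "dend", parent = 2L))
  new_neuron(secs, Ra = Ra)
}

#' @rdname toy_builders
#' @export
build_diameter_step_cell <- function(soma_d = 20, dend_d = 5, ratio = 1,
                                     seg_len = 300, Ra = HH_CONST$Ra) {
  soma_d <- as_um(soma_d); dend_d <- as_um(dend_d); seg_len <- as_um(seg_len)
  stopifnot(ratio > 0)
  p0 <- c(soma_d / 2, 0, 0)
  p1 <- p0 + c(seg_len, 0, 0)
  p2 <- p1 + c(seg_len, 0, 0)
  secs <- list(
    soma_section(soma_d),
    new_section(rbind(p0, p1), diam = dend_d, tag = "dend", parent = 1L),
    new_section(rbind(p1, p2), diam = dend_d / ratio, tag = "dend",
                parent = 2L))
  new_neuron(secs, Ra = Ra)
}

#' @rdname toy_builders
#' @export
build_soma_myelinated_axon <- function(soma_d = 20, internode_d = 1,
                                       node_d = 0.75, internode_len = 100,
                                       node_len = 1, n_internodes = 20,
                                       Ra = HH_CONST$Ra) {
  soma_d <- as_um(soma_d); internode_d <- as_um(internode_d)
  node_d <- as_um(node_d); internode_len <- as_um(internode_len)
  node_len <- as_um(node_len)
  stopifnot(n_internodes >= 1)
  secs <- list(soma_section(soma_d))
  x <- soma_d / 2
  parent <- 1L
  for (i in seq_len(n_internodes)) {
    secs[[length(secs) + 1L]] <-
      new_section(rbind(c(x, 0, 0), c(x + internode_len, 0, 0)),
                  diam = internode_d, tag = "myelin", parent = parent)
    x <- x + internode_len
    parent <- length(secs)
    secs[[length(secs) + 1L]] <-
      new_section(rbind(c(x, 0, 0), c(x + node_len, 0, 0)),
                  diam = node_d, tag = "node", parent = parent)
    x <- x + node_len
    parent <- length(secs)
  }
  new_neuron(secs, Ra = Ra)
}

#' Build a toy neuron from a descriptor list
#'
#' Dispatch layer used by the config interface: `spec$kind` selects the
#' builder (`straight_axon`, `soma_dendrites`, `bent_dendrite_cell`,
#' `bifurcation_cell`, `diameter_step_cell`, `soma_myelinated_axon`) and the
#' remaining entries are passed as arguments.
#'
#' @param spec named list descriptor with a `kind` entry.
#' @return an `ms_neuron`.
#' @export
build_toy <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  builder <- switch(spec$kind,
    straight_axon        = build_straight_axon,
    soma_dendrites       = build_soma_dendrites,
    bent_dendrite_cell   = build_bent_dendrite_cell,
    bifurcation_cell     = build_bifurcation_cell,
    diameter_step_cell   = build_diameter_step_cell,
    soma_myelinated_axon = build_soma_myelinated_axon,
    stop("unknown toy geometry kind: ", spec$kind, call. = FALSE))
  args <- spec[setdiff(names(spec), "kind")]
  # YAML 1.1 reads a bare key `n` as a boolean; configs use `n_dendrites`
  names(args)[names(args) == "n_dendrites"] <- "n"
  if (any(names(args) %in% c("TRUE", "FALSE")))
    stop("a YAML key parsed as a boolean (YAML treats bare 'n'/'y' as ",
         "booleans); write 'n_dendrites' for the dendrite count",
         call. = FALSE)
  do.call(builder, args)
}

#' Rigid in-plane transform of a neuron
#'
#' Rotates the neuron about the origin (z axis) by `rotation` degrees, then
#' translates by `offset` in the neuron plane. Connectivity, diameters,
#' length and membrane area are unchanged. Shifting the neuron by (a, b) is
#' equivalent to shifting the coil center by (-a, -b).
#'
#' @param neuron an `ms_neuron`.
#' @param offset length-2 in-plane translation, um (or unit strings).
#' @param rotation rotation angle, degrees counterclockwise.
#' @return the transformed `ms_neuron`.
#' @export
place <- function(neuron, offset = c(0, 0), rotation = 0) {
  stopifnot(inherits(neuron, "ms_neuron"), length(offset) == 2)
  offset <- as_um(offset)
  R <- rot2(rotation)
  neuron$sections <- lapply(neuron$sections, function(s) {
    xy <- s$points[, 1:2, drop = FALSE] %*% t(R)
    s$points[, 1] <- xy[, 1] + offset[1]
    s$points[, 2] <- xy[, 2] + offset[2]
    s
  })
  neuron
}
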