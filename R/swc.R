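# SWC morphology reader/writer (standard 7-column format, '#' comments).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a neuron morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments). The point tree is split into unbranched sections at branch
#' points and at diameter or type changes; SWC radii become diameters. A
#' single-point soma (type 1) becomes a sphere-equivalent cylinder with
#' length equal to its diameter, oriented along x, to which children attach
#' at midpoint. Each child section's polyline starts at its parent point, so
#' the SWC path geometry is preserved. Type codes map to mechanism tags:
#' 1 soma, 2 axon, all others dend.
#'
#' @param con file path or connection.
#' @param Ra axial resistivity (Ohm*cm) to attach to the neuron.
#' @param planar mark the neuron as planar; default: autodetect (all z = 0).
#' @return an `ms_neuron`.
#' @export
load_swc <- function(con, Ra = HH_CONST$Ra, planar = NULL) {
  lines <- readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln_no <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  if (length(rows) == 0) stop("empty SWC file", call. = FALSE)
  dat <- matrix(NA_real_, nrow = length(rows), ncol = 7)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != 7)
      stop("SWC parse error at line ", ln_no[i], ": expected 7 columns",
           call. = FALSE)
    dat[i, ] <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(dat[i, ]))
      stop("SWC parse error at line ", ln_no[i], ": non-numeric field",
           call. = FALSE)
  }
  id <- dat[, 1]; type <- dat[, 2]; xyz <- dat[, 3:5, drop = FALSE]
  radius <- dat[, 6]; parent <- dat[, 7]
  pid <- rep(NA_integer_, length(id))
  for (i in seq_along(id)) {
    if (radius[i] <= 0)
      stop("SWC parse error at line ", ln_no[i], ": non-positive radius",
           call. = FALSE)
    if (parent[i] != -1) {
      p <- match(parent[i], id[seq_len(i - 1L)])
      if (is.na(p))
        stop("SWC parse error at line ", ln_no[i], ": unknown parent id ",
             parent[i], " (parents must be defined on earlier lines)",
             call. = FALSE)
      pid[i] <- p
    }
  }
  tag_of <- function(tp) switch(as.character(tp), "1" = "soma",
                                "2" = "axon", "dend")
  nchild <- tabulate(pid[!is.na(pid)], nbins = length(id))
  single_soma <- sum(type == 1) == 1
  sections <- list()      # each: points, diam, tag, parent, parent_pos
  soma_center <- NULL     # set for a single-point soma section
  sec_of_point <- integer(length(id))
  pending <- logical(0)   # per-section: only the root point so far
  for (i in seq_along(id)) {
    if (is.na(pid[i])) {
      if (type[i] == 1 && single_soma) {
        r <- radius[i]
        sections[[length(sections) + 1L]] <- new_section(
          rbind(xyz[i, ] - c(r, 0, 0), xyz[i, ] + c(r, 0, 0)),
          diam = 2 * r, tag = "soma", parent = 0L, parent_pos = 0.5)
        soma_center <- xyz[i, ]
        pending[length(sections)] <- FALSE
      } else {
        sections[[length(sections) + 1L]] <-
          list(points = xyz[i, , drop = FALSE], diam = 2 * radius[i],
               tag = tag_of(type[i]), parent = 0L, parent_pos = 1)
        pending[length(sections)] <- TRUE
      }
      sec_of_point[i] <- length(sections)
      next
    }
    p <- pid[i]
    psec <- sec_of_point[p]
    if (pending[psec]) {
      sections[[psec]]$points <- rbind(sections[[psec]]$points, xyz[i, ])
      sections[[psec]]$diam <- 2 * radius[i]
      sections[[psec]]$tag <- tag_of(type[i])
      pending[psec] <- FALSE
      sec_of_point[i] <- psec
    } else if (nchild[p] == 1 &&
               identical(sections[[psec]]$tag, tag_of(type[i])) &&
               abs(sections[[psec]]$diam - 2 * radius[i]) < 1e-9 &&
               all(sections[[psec]]$points[nrow(sections[[psec]]$points), ] ==
                   xyz[p, ])) {
      sections[[psec]]$points <- rbind(sections[[psec]]$points, xyz[i, ])
      sec_of_point[i] <- psec
    } else {
      # new section anchored at the parent point
      is_soma_root <- !is.null(soma_center) && psec == 1L &&
        all(xyz[p, ] == soma_center)
      ppos <- if (is_soma_root) 0.5 else {
        pts <- sections[[psec]]$points
        d <- sqrt(rowSums((pts - matrix(xyz[p, ], nrow(pts), 3,
                                        byrow = TRUE))^2))
        j <- which.min(d)
        cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
        cl[j] / cl[length(cl)]
      }
      sections[[length(sections) + 1L]] <- new_section(
        rbind(xyz[p, ], xyz[i, ]), diam = 2 * radius[i],
        tag = tag_of(type[i]), parent = psec, parent_pos = ppos)
      pending[length(sections)] <- FALSE
      sec_of_point[i] <- length(sections)
    }
  }
  if (any(pending)) stop("SWC file contains an isolated point", call. = FALSE)
  z <- unlist(lapply(sections, function(s) s$points[, 3]))
  if (is.null(planar)) planar <- all(abs(z) < 1e-9)
  new_neuron(sections, Ra = Ra, planar = planar)
}

#' Write a neuron to an SWC file
#'
#' Inverse of [load_swc()] for chain-contiguous morphologies (each child
#' section starting at its parent's endpoint): a write-then-read round trip
#' preserves coordinates and diameters. Mid-section attachments (dendrites
#' radiating from a soma center) are recorded against the nearest parent
#' sample point.
#'
#' @param neuron an `ms_neuron`; @param path output file path.
#' @return invisibly, `path`.
#' @export
write_swc <- function(neuron, path) {
  stopifnot(inherits(neuron, "ms_neuron"))
  type_of <- function(tag) switch(tag, soma = 1L, axon = 2L, node = 2L,
                                  myelin = 2L, 3L)
  rows <- list()
  next_id <- 1L
  last_id <- integer(length(neuron$sections))
  end_pt <- vector("list", length(neuron$sections))
  for (i in seq_along(neuron$sections)) {
    s <- neuron$sections[[i]]
    pts <- s$points
    # a root soma written as the sphere-equivalent cylinder collapses back
    # to its single SWC sample point
    if (i == 1L && s$parent == 0L && s$tag == "soma" && nrow(pts) == 2 &&
        abs(sqrt(sum((pts[2, ] - pts[1, ])^2)) - s$diam) < 1e-9) {
      ctr <- (pts[1, ] + pts[2, ]) / 2
      rows[[length(rows) + 1L]] <- c(next_id, 1L, ctr, s$diam / 2, -1L)
      last_id[i] <- next_id
      end_pt[[i]] <- ctr
      next_id <- next_id + 1L
      next
    }
    start_row <- 1L
    parent_id <- -1L
    if (s$parent > 0L) {
      parent_id <- last_id[s$parent]
      if (max(abs(pts[1, ] - end_pt[[s$parent]])) < 1e-9) start_row <- 2L
    }
    for (j in start_row:nrow(pts)) {
      rows[[length(rows) + 1L]] <-
        c(next_id, type_of(s$tag), pts[j, ], s$diam / 2, parent_id)
      parent_id <- next_id
      next_id <- next_id + 1L
    }
    last_id[i] <- next_id - 1L
    end_pt[[i]] <- pts[nrow(pts), ]
  }
  m <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by magstim", con)
  for (k in seq_len(nrow(m)))
    writeLines(paste(c(sprintf("%d", m[k, 1]), sprintf("%d", m[k, 2]),
                       sprintf("%.9g", m[k, 3:6]), sprintf("%d", m[k, 7])),
                     collapse = " "), con)
  invisible(path)
}
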