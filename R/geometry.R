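#' Scanner geometry for a four-level SiPM PET detector ring
#'
#' Builds the crystal hierarchy of a digital-photon-counting PET ring:
#' 18 modules around the ring, each module holding 4 (tangential) x 5 (axial)
#' stacks, each stack 4 x 4 dice, each die 2 x 2 LYSO crystals with 1:1 SiPM
#' coupling -- 23 040 crystals in total. Crystals within a die sit at the
#' bare 4 mm crystal pitch; a single derived packing pitch is inserted at
#' every die/stack/module boundary so that the 576 tangential positions close
#' the ring of the stated inner diameter and the 40 axial rows span the
#' axial field of view.
#'
#' All lengths are millimetres. The coordinate frame is right-handed with Z
#' along the scanner axis, origin at the transverse and axial centre.
#'
#' @param ring_inner_diameter Inner diameter of the detector cylinder (mm).
#' @param axial_fov Axial field of view (mm).
#' @param n_modules Number of modules in the ring.
#' @param stacks_per_module Tangential and axial stack counts per module.
#' @param dice_per_stack Tangential and axial die counts per stack.
#' @param crystals_per_die Tangential and axial crystal counts per die.
#' @param crystal_size Crystal dimensions (tangential, axial, depth) in mm.
#' @return An object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(ring_inner_diameter = 764,
                             axial_fov = 164,
                             n_modules = 18L,
                             stacks_per_module = c(4L, 5L),
                             dice_per_stack = c(4L, 4L),
                             crystals_per_die = c(2L, 2L),
                             crystal_size = c(4, 4, 19)) {
  stopifnot(ring_inner_diameter > 0, axial_fov > 0, n_modules >= 1)
  n_tang_mod <- stacks_per_module[1] * dice_per_stack[1] * crystals_per_die[1]
  n_ax <- stacks_per_module[2] * dice_per_stack[2] * crystals_per_die[2]
  n_tang <- n_modules * n_tang_mod
  n_crystals <- n_tang * n_ax

  pitch <- crystal_size[1]
  # tangential: in-die intervals at the crystal pitch, one shared boundary
  # pitch at every die/stack/module seam, sized so the ring closes
  circ <- pi * ring_inner_diameter
  n_die_t <- n_tang / crystals_per_die[1]             # dice around the ring
  n_in_die_t <- n_tang - n_die_t                      # in-die intervals
  n_bound_t <- n_tang - n_in_die_t                    # boundary intervals
  gap_t <- (circ - n_in_die_t * pitch) / n_bound_t
  if (gap_t < pitch)
    stop("ring too small for requested crystal packing")

  # axial: centers must span axial_fov - one crystal width
  ax_pitch <- crystal_size[2]
  n_die_a <- n_ax / crystals_per_die[2]
  n_in_die_a <- n_ax - n_die_a
  n_bound_a <- (n_ax - 1) - n_in_die_a
  gap_a <- (axial_fov - ax_pitch - n_in_die_a * ax_pitch) / n_bound_a

  # arc-length offsets of the tangential positions within one module
  t_idx <- seq_len(n_tang_mod) - 1L
  step_t <- ifelse(t_idx[-1] %% crystals_per_die[1] == 0, gap_t, pitch)
  off_t <- c(0, cumsum(step_t))
  module_arc <- circ / n_modules

  a_idx <- seq_len(n_ax) - 1L
  step_a <- ifelse(a_idx[-1] %% crystals_per_die[2] == 0, gap_a, ax_pitch)
  z_rows <- c(0, cumsum(step_a))
  z_rows <- z_rows - (min(z_rows) + max(z_rows)) / 2

  # global tangential angles (radians) of all n_tang positions
  arc_all <- rep(seq_len(n_modules) - 1L, each = n_tang_mod) * module_arc +
    rep(off_t, n_modules)
  radius <- ring_inner_diameter / 2
  structure(list(
    ring_inner_diameter = ring_inner_diameter,
    radius = radius,
    axial_fov = axial_fov,
    n_modules = as.integer(n_modules),
    stacks_per_module = as.integer(stacks_per_module),
    dice_per_stack = as.integer(dice_per_stack),
    crystals_per_die = as.integer(crystals_per_die),
    crystal_size = crystal_size,
    n_tang_module = as.integer(n_tang_mod),
    n_tang = as.integer(n_tang),
    n_axial = as.integer(n_ax),
    n_crystals = as.integer(n_crystals),
    gap_tangential = gap_t,
    gap_axial = gap_a,
    angles = arc_all / radius,
    z_rows = z_rows
  ), class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "scanner_geometry: %d crystals (%d tangential x %d axial), ring ID %.0f mm, axial FOV %.0f mm\n",
    x$n_crystals, x$n_tang, x$n_axial, x$ring_inner_diameter, x$axial_fov))
  invisible(x)
}

#' Convert hierarchical crystal indices to flat ids
#'
#' Flat ids run 0..(n_crystals - 1). All components are 0-based:
#' `module`, tangential/axial stack, die and crystal indices.
#'
#' @param geom A `scanner_geometry`.
#' @param module,stack_t,stack_a,die_t,die_a,cr_t,cr_a Integer vectors
#'   (recycled to a common length).
#' @return Integer vector of flat crystal ids.
#' @export
crystal_flat_id <- function(geom, module, stack_t, stack_a, die_t, die_a, cr_t, cr_a) {
  d <- data.frame(module, stack_t, stack_a, die_t, die_a, cr_t, cr_a)
  with(geom, {
    ok <- d$module >= 0 & d$module < n_modules &
      d$stack_t >= 0 & d$stack_t < stacks_per_module[1] &
      d$stack_a >= 0 & d$stack_a < stacks_per_module[2] &
      d$die_t >= 0 & d$die_t < dice_per_stack[1] &
      d$die_a >= 0 & d$die_a < dice_per_stack[2] &
      d$cr_t >= 0 & d$cr_t < crystals_per_die[1] &
      d$cr_a >= 0 & d$cr_a < crystals_per_die[2]
    if (!all(ok)) stop("crystal index out of range")
    tang <- d$stack_t * dice_per_stack[1] * crystals_per_die[1] +
      d$die_t * crystals_per_die[1] + d$cr_t
    ax <- d$stack_a * dice_per_stack[2] * crystals_per_die[2] +
      d$die_a * crystals_per_die[2] + d$cr_a
    as.integer(ax + n_axial * (tang + n_tang_module * d$module))
  })
}

#' Decompose flat crystal ids into the detector hierarchy
#'
#' Inverse of [crystal_flat_id()].
#'
#' @param geom A `scanner_geometry`.
#' @param flat_id Integer vector of flat ids in `0..(n_crystals-1)`.
#' @return A `data.frame` with 0-based columns `module`, `stack_t`, `stack_a`,
#'   `die_t`, `die_a`, `cr_t`, `cr_a`, plus `tang` and `ax` (position within
#'   module / axial row index).
#' @export
crystal_index <- function(geom, flat_id) {
  if (any(flat_id < 0 | flat_id >= geom$n_crystals))
    stop("flat_id out of range 0..", geom$n_crystals - 1L)
  flat_id <- as.integer(flat_id)
  ax <- flat_id %% geom$n_axial
  rest <- flat_id %/% geom$n_axial
  tang <- rest %% geom$n_tang_module
  module <- rest %/% geom$n_tang_module
  cpd <- geom$crystals_per_die
  dps <- geom$dice_per_stack
  data.frame(
    module = module,
    stack_t = tang %/% (dps[1] * cpd[1]),
    stack_a = ax %/% (dps[2] * cpd[2]),
    die_t = (tang %/% cpd[1]) %% dps[1],
    die_a = (ax %/% cpd[2]) %% dps[2],
    cr_t = tang %% cpd[1],
    cr_a = ax %% cpd[2],
    tang = tang,
    ax = ax
  )
}

#' 3D positions of crystal centers
#'
#' Returns the front-face center of each crystal, projected onto the
#' detector cylinder (no depth-of-interaction offset).
#'
#' @param geom A `scanner_geometry`.
#' @param flat_id Integer vector of flat crystal ids.
#' @return A `data.frame` with columns `x`, `y`, `z` (mm).
#' @export
crystal_position <- function(geom, flat_id) {
  if (any(flat_id < 0 | flat_id >= geom$n_crystals))
    stop("flat_id out of range 0..", geom$n_crystals - 1L)
  flat_id <- as.integer(flat_id)
  ax <- flat_id %% geom$n_axial
  gtang <- flat_id %/% geom$n_axial      # global tangential index
  ang <- geom$angles[gtang + 1L]
  data.frame(
    x = geom$radius * cos(ang),
    y = geom$radius * sin(ang),
    z = geom$z_rows[ax + 1L]
  )
}

#' Map a cylinder hit to the nearest crystal
#'
#' Given hit angles and axial coordinates on the detector cylinder, returns
#' the flat id of the nearest crystal center, or `NA` when the hit falls
#' outside the axial acceptance (beyond half a crystal width past the outer
#' rows).
#'
#' @param geom A `scanner_geometry`.
#' @param angle Azimuth of the hit (radians).
#' @param z Axial coordinate of the hit (mm).
#' @return Integer vector of flat crystal ids (`NA` for misses).
#' @export
nearest_crystal <- function(geom, angle, z) {
  zmax <- max(geom$z_rows) + geom$crystal_size[2] / 2
  miss <- abs(z) > zmax
  # nearest axial row
  arow <- findInterval(z, (geom$z_rows[-1] + geom$z_rows[-geom$n_axial]) / 2)
  # nearest tangential position, circular
  ang <- angle %% (2 * pi)
  bnd <- (geom$angles[-1] + geom$angles[-geom$n_tang]) / 2
  wrap_mid <- (geom$angles[geom$n_tang] + geom$angles[1] + 2 * pi) / 2
  gt <- findInterval(ang, c(bnd, wrap_mid)) %% geom$n_tang
  module <- gt %/% geom$n_tang_module
  tang <- gt %% geom$n_tang_module
  id <- as.integer(arow + geom$n_axial * (tang + geom$n_tang_module * module))
  id[miss] <- NA_integer_
  id
}

#' Line of response between two crystals
#'
#' Computes LOR endpoints and sinogram coordinates for crystal pairs. The
#' radial offset `s` is the signed perpendicular distance from the scanner
#' axis to the LOR in the transverse plane, signed along the LOR normal
#' `(cos(phi), sin(phi))` with azimuth `phi` in `[0, pi)`; it is therefore
#' independent of the endpoint order.
#'
#' @param geom A `scanner_geometry`.
#' @param id1,id2 Flat crystal ids (vectors, recycled).
#' @return A `data.table` with endpoint columns `x1..z2`, radial offset `s`,
#'   azimuth `phi` and axial midpoint `zmid`.
#' @export
lor_of <- function(geom, id1, id2) {
  if (any(id1 == id2)) stop("LOR requires two distinct crystals")
  p1 <- crystal_position(geom, id1)
  p2 <- crystal_position(geom, id2)
  lor_table(p1$x, p1$y, p1$z, p2$x, p2$y, p2$z)
}

# sinogram coordinates from raw endpoints
lor_table <- function(x1, y1, z1, x2, y2, z2) {
  alpha <- atan2(y2 - y1, x2 - x1)
  phi <- (alpha + pi / 2) %% pi
  s <- x1 * cos(phi) + y1 * sin(phi)
  data.table::data.table(
    x1 = x1, y1 = y1, z1 = z1, x2 = x2, y2 = y2, z2 = z2,
    s = s, phi = phi, zmid = (z1 + z2) / 2
  )
}

#' Arc correction: resample LOR radial offsets onto a uniform grid
#'
#' The ring geometry samples the radial sinogram coordinate non-uniformly
#' (denser toward the edge of the transverse FOV). Arc correction snaps each
#' LOR's radial offset `s` to the nearest center of a uniform grid of pitch
#' `1/rate` mm whose cell boundaries are centred on `s = 0` (grid centers at
#' +-0.25, +-0.75, ... mm for the default 2 LOR/mm). Ties at a cell boundary
#' are broken toward positive `s`. The LOR endpoints are translated along
#' the LOR normal so that the stored endpoints stay consistent with the
#' corrected `s`; `phi`, `zmid` and the event count are unchanged.
#'
#' @param lors A `data.table` as returned by [lor_of()] (possibly with extra
#'   event columns, which are preserved).
#' @param rate Radial sampling rate in LOR per mm (default 2).
#' @return The corrected `data.table` (a copy).
#' @export
arc_correct <- function(lors, rate = 2) {
  stopifnot(rate > 0)
  out <- data.table::copy(data.table::as.data.table(lors))
  s_new <- (floor(out$s * rate) + 0.5) / rate
  ds <- s_new - out$s
  nx <- cos(out$phi)
  ny <- sin(out$phi)
  out[, `:=`(
    x1 = x1 + ds * nx, y1 = y1 + ds * ny,
    x2 = x2 + ds * nx, y2 = y2 + ds * ny,
    s = s_new
  )]
  out[]
}

#' Write crystal positions to CSV
#'
#' Dumps `flat_id, x, y, z` for every crystal; used by the `geometry dump`
#' CLI verb.
#'
#' @param geom A `scanner_geometry`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
geometry_dump <- function(geom, path) {
  ids <- seq_len(geom$n_crystals) - 1L
  pos <- crystal_position(geom, ids)
  data.table::fwrite(cbind(flat_id = ids, pos), path)
  invisible(path)
}
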