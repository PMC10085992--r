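# Time-reversal recording, phase conjugation, and refocus verification.

#' Define a set of focal targets
#'
#' @param points physical coordinates of the intended foci, meters: a matrix
#'   with one row per target (or a vector for a single target).
#' @param f0 drive frequency, Hz.
#' @param weights relative drive amplitudes, one per target (default 1).
#' @return a `target_set` object.
#' @export
target_set <- function(points, f0, weights = 1) {
  points <- if (is.matrix(points)) points else matrix(points, nrow = 1L)
  check_positive_scalar(f0, "f0")
  weights <- rep_len(weights, nrow(points))
  if (any(weights <= 0)) abort("target weights must be > 0")
  structure(list(points = points, f0 = f0, weights = weights),
            class = "target_set")
}

#' Define the recording/emission plane
#'
#' The plane is a grid slice: all voxels with a fixed index along the normal
#' `axis`. In 2D the "plane" is a line of pixels. `span` restricts the
#' in-plane extent; by default the outermost `margin` voxels per side are
#' excluded so that no pixel sits inside the absorbing boundary layer.
#'
#' @param axis normal axis (1 = x, 2 = y, 3 = z).
#' @param index voxel index of the plane along the normal axis.
#' @param span list of index vectors for the in-plane axes (in axis order,
#'   skipping the normal axis), or NULL for the default.
#' @param margin voxels excluded at each in-plane edge when `span` is NULL.
#' @return a `recording_plane` object.
#' @export
recording_plane <- function(axis, index, span = NULL, margin = 12L) {
  structure(list(axis = as.integer(axis), index = as.integer(index),
                 span = span, margin = as.integer(margin)),
            class = "recording_plane")
}

# resolve a plane against a grid: pixel index matrix + layout
plane_pixels <- function(plane, grid) {
  nd <- grid_ndim(grid)
  if (plane$axis < 1L || plane$axis > nd) abort("plane axis outside the grid")
  if (plane$index < 1L || plane$index > grid$n[plane$axis]) {
    abort("plane index outside the grid")
  }
  in_axes <- setdiff(which(grid$n > 1L), plane$axis)
  span <- plane$span
  if (is.null(span)) {
    span <- lapply(in_axes, function(a) {
      lo <- min(plane$margin + 1L, grid$n[a])
      hi <- max(grid$n[a] - plane$margin, lo)
      lo:hi
    })
  }
  if (length(span) != length(in_axes)) {
    abort("`span` must give one index vector per in-plane axis")
  }
  layout <- vapply(span, length, 1L)
  combos <- as.matrix(expand.grid(span))
  idx <- matrix(plane$index, nrow = nrow(combos), ncol = nd)
  for (j in seq_along(in_axes)) idx[, in_axes[j]] <- combos[, j]
  list(idx = idx, layout = layout, in_axes = in_axes, span = span)
}

# internal phase_map constructor
new_phase_map <- function(phase, amplitude, pitch, plane, in_axes, span,
                          grid, f0) {
  structure(list(phase = phase, amplitude = amplitude, pitch = pitch,
                 plane = plane, in_axes = in_axes, span = span,
                 grid = grid, f0 = f0),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  dims <- dim(x$phase) %||% length(x$phase)
  cat(sprintf("phase_map: %s pixels, pitch %.3g mm, f0 %.3g MHz\n",
              paste(dims, collapse = " x "), x$pitch * 1e3, x$f0 / 1e6))
  invisible(x)
}

# physical coordinates of every plane pixel (matrix, cols = grid axes)
phase_map_coords <- function(map) {
  grid <- map$grid
  combos <- as.matrix(expand.grid(map$span))
  nd <- grid_ndim(grid)
  idx <- matrix(map$plane$index, nrow = nrow(combos), ncol = nd)
  for (j in seq_along(map$in_axes)) idx[, map$in_axes[j]] <- combos[, j]
  index_to_coord(grid, idx)
}

#' Record a time-reversal phase map through the medium
#'
#' Drives every target point simultaneously as a monochromatic source at the
#' target set's `f0` (given relative weights, zero relative phase), lets the
#' field reach a sinusoidal steady state, and extracts phase and amplitude
#' at every recording-plane pixel with [steady_state_phase()]. Conjugating
#' the result yields the excitation map that refocuses on the targets.
#'
#' @param medium a [medium_map()].
#' @param targets a [target_set()].
#' @param plane a [recording_plane()].
#' @param n_cycles number of drive cycles; at least 20 are required to
#'   reach a clean steady state. Propagation time from the farthest target
#'   to the plane is added automatically.
#' @param cfl,boundary solver controls.
#' @param discard fraction of the trace discarded before phase extraction.
#' @return a `phase_map`.
#' @export
record_time_reversal <- function(medium, targets, plane, n_cycles = 20,
                                 cfl = 0.3, boundary = boundary_spec(),
                                 discard = 0.6) {
  stopifnot(inherits(medium, "medium_map"), inherits(targets, "target_set"),
            inherits(plane, "recording_plane"))
  if (n_cycles < 20) {
    abort("n_cycles = %g is below the minimum of 20 drive cycles", n_cycles)
  }
  grid <- medium$grid
  f0 <- targets$f0
  tgt_idx <- coord_to_index(grid, targets$points)
  if (any(tgt_idx[, plane$axis] == plane$index)) {
    abort("recording plane intersects a target")
  }
  px <- plane_pixels(plane, grid)
  # propagation allowance: farthest target-to-pixel distance at slowest speed
  tgt_xy <- index_to_coord(grid, tgt_idx)
  px_xy <- index_to_coord(grid, px$idx)
  dmax <- 0
  for (i in seq_len(nrow(tgt_xy))) {
    dmax <- max(dmax, sqrt(rowSums(sweep(px_xy, 2L, tgt_xy[i, ], `-`)^2)))
  }
  travel_cycles <- ceiling(dmax / min(medium$c0) * f0)
  duration <- (n_cycles + travel_cycles) / f0
  src <- source_spec(tgt_idx, f0 = f0, amplitude = targets$weights)
  rec <- run_simulation(medium, src, px$idx, duration, cfl = cfl,
                        boundary = boundary, f0 = f0)
  ss <- steady_state_phase(rec, f0, discard = discard)
  shape <- function(v) if (length(px$layout) > 1L) array(v, px$layout) else v
  new_phase_map(shape(ss$phase), shape(ss$amplitude), grid$dx, plane,
                px$in_axes, px$span, grid, f0)
}

#' Conjugate a phase map
#'
#' Negates the phase (time reversal for a monochromatic field) and rewraps
#' into (-pi, pi]; the amplitude is untouched. Applying it twice returns the
#' original map.
#'
#' @param map a `phase_map`.
#' @return the conjugated `phase_map`.
#' @export
conjugate_phase <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  map$phase <- wrap_phase(-map$phase)
  map
}

#' Geometric (Fresnel) focusing phase map
#'
#' The uncompensated reference: a purely geometric lens phase
#' `phase(x, y) = k (sqrt(z^2 + x^2 + y^2) - z)` (wrapped), with `(x, y)`
#' the lateral offset from the focus and `z` the plane-to-focus axial
#' distance. The sign follows the package's demodulation convention
#' `p ~ A sin(2 pi f0 t + phase)`, under which propagation over a path `r`
#' contributes `-k r`, so a focusing emission profile must advance the
#' off-axis pixels by `+k (r - z)`. In homogeneous media this map and a
#' conjugated time-reversal recording agree up to a constant; through an
#' aberrator they do not -- that difference is the whole point of skull
#' compensation.
#'
#' @param plane a [recording_plane()].
#' @param focus physical focus coordinate, meters.
#' @param f0 drive frequency, Hz.
#' @param c sound speed of the homogeneous reference medium, m/s.
#' @param grid the `sim_grid` the plane lives on.
#' @return a `phase_map`.
#' @export
fresnel_phase <- function(plane, focus, f0, c, grid) {
  stopifnot(inherits(plane, "recording_plane"), inherits(grid, "sim_grid"))
  px <- plane_pixels(plane, grid)
  coords <- index_to_coord(grid, px$idx)
  plane_pos <- grid$origin[plane$axis] + (plane$index - 1) * grid$dx
  z <- abs(focus[plane$axis] - plane_pos)
  if (z <= 0) abort("focus must lie beyond the plane")
  lat2 <- rep(0, nrow(coords))
  for (a in px$in_axes) lat2 <- lat2 + (coords[, a] - focus[a])^2
  k <- 2 * pi * f0 / c
  ph <- wrap_phase(k * (sqrt(z^2 + lat2) - z))
  shape <- function(v) if (length(px$layout) > 1L) array(v, px$layout) else v
  new_phase_map(shape(ph), shape(rep(1, length(ph))), grid$dx, plane,
                px$in_axes, px$span, grid, f0)
}

#' Laterally steer a phase map
#'
#' Translates the map by a whole number of pixels (the physical analogue of
#' sliding the printed lens across the aperture). Vacated pixels are filled
#' by replicating the nearest edge value.
#'
#' @param map a `phase_map`.
#' @param offset lateral displacement, meters, one entry per in-plane axis.
#'   Must be an integer multiple of the pixel pitch.
#' @return the steered `phase_map`.
#' @export
steer_map <- function(map, offset) {
  stopifnot(inherits(map, "phase_map"))
  offset <- rep_len(offset, length(map$in_axes))
  shift <- offset / map$pitch
  if (any(abs(shift - round(shift)) > 1e-6)) {
    abort("offset must be an integer multiple of the pixel pitch %.3g m",
          map$pitch)
  }
  shift <- as.integer(round(shift))
  dims <- dim(map$phase) %||% length(map$phase)
  shift_one <- function(x) {
    for (j in seq_along(shift)) {
      if (shift[j] == 0L) next
      n <- dims[j]
      src <- pmin(pmax(seq_len(n) - shift[j], 1L), n)
      idx <- lapply(dims, seq_len)
      idx[[j]] <- src
      x <- do.call(`[`, c(list(array(x, dims)), idx, list(drop = FALSE)))
    }
    array(x, dims)
  }
  map$phase <- if (length(dims) > 1L) shift_one(map$phase) else {
    as.vector(shift_one(map$phase))
  }
  map$amplitude <- if (length(dims) > 1L) shift_one(map$amplitude) else {
    as.vector(shift_one(map$amplitude))
  }
  map
}

#' Re-emit a conjugated phase map and map the refocused field
#'
#' Drives every plane pixel as a monochromatic source with the map's phases
#' (uniform amplitude by default -- a passive phase-only lens over a uniform
#' planar transducer; `amplitude = "recorded"` weights pixels by the
#' recorded amplitude instead), runs to a sinusoidal steady state, and
#' returns the demodulated pressure-amplitude field over the whole grid.
#'
#' @param medium a [medium_map()].
#' @param map the conjugated `phase_map` (on the same plane used for
#'   recording).
#' @param n_cycles drive cycles (propagation time across the grid is added
#'   automatically).
#' @param amplitude "uniform" or "recorded".
#' @param region optional evaluation region, `list(lo = , hi = )` physical
#'   corner coordinates in meters (e.g. the scanned cavity volume); the
#'   returned field is cropped to it.
#' @param cfl,boundary solver controls.
#' @param integrate_cycles demodulation window, periods.
#' @return a [field_volume()] of steady-state pressure amplitude, Pa.
#' @export
verify_refocus <- function(medium, map, n_cycles = 20,
                           amplitude = c("uniform", "recorded"),
                           region = NULL, cfl = 0.3,
                           boundary = boundary_spec(), integrate_cycles = 5) {
  stopifnot(inherits(medium, "medium_map"), inherits(map, "phase_map"))
  amplitude <- match.arg(amplitude)
  grid <- medium$grid
  px <- plane_pixels(recording_plane(map$plane$axis, map$plane$index,
                                     span = map$span), grid)
  if (nrow(px$idx) != length(map$phase)) {
    abort("phase map layout does not match the plane on this grid")
  }
  amp <- if (amplitude == "uniform") rep(1, nrow(px$idx)) else {
    as.vector(map$amplitude) / max(map$amplitude)
  }
  f0 <- map$f0
  # propagation allowance: farthest pixel-to-corner distance
  px_xy <- index_to_coord(grid, px$idx)
  lo <- grid$origin; hi <- grid$origin + (grid$n - 1) * grid$dx
  corners <- as.matrix(expand.grid(lapply(seq_along(lo),
                                          function(a) c(lo[a], hi[a]))))
  dmax <- 0
  for (i in seq_len(nrow(corners))) {
    dmax <- max(dmax, sqrt(rowSums(sweep(px_xy, 2L, corners[i, ], `-`)^2)))
  }
  travel_cycles <- ceiling(dmax / min(medium$c0) * f0)
  src <- source_spec(px$idx, f0 = f0, amplitude = amp,
                     phase = as.vector(map$phase))
  ss <- steady_state_field(medium, src, f0,
                           n_cycles = n_cycles + travel_cycles,
                           integrate_cycles = integrate_cycles, cfl = cfl,
                           boundary = boundary)
  out <- field_volume(grid, ss$amplitude)
  if (!is.null(region)) out <- crop_field(out, region$lo, region$hi)
  out
}

#' Crop a field volume to a physical box
#'
#' @param field a [field_volume()].
#' @param lo,hi physical corner coordinates, meters.
#' @return the cropped `field_volume` (its grid origin is adjusted).
#' @export
crop_field <- function(field, lo, hi) {
  grid <- field$grid
  nd <- grid_ndim(grid)
  lo <- rep_len(lo, nd); hi <- rep_len(hi, nd)
  idx <- lapply(seq_len(nd), function(a) {
    xs <- axis_coords(grid, a)
    which(xs >= lo[a] & xs <= hi[a])
  })
  if (any(vapply(idx, length, 1L) == 0L)) abort("empty crop region")
  amp <- do.call(`[`, c(list(field$amplitude), idx, list(drop = FALSE)))
  origin <- vapply(seq_len(nd),
                   function(a) axis_coords(grid, a)[idx[[a]][1L]], 0)
  field_volume(sim_grid(vapply(idx, length, 1L), grid$dx, origin), amp)
}
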