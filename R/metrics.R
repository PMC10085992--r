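# Quantitative evaluation of pressure fields: profiles, FWHM, focal
# localization, multifocus detection, interface diagnostics.

#' Pressure-amplitude field container
#'
#' @param grid a [sim_grid()].
#' @param amplitude non-negative pressure amplitude per voxel, Pa (array of
#'   dim `grid$n`).
#' @return a `field_volume` object.
#' @export
field_volume <- function(grid, amplitude) {
  stopifnot(inherits(grid, "sim_grid"))
  amplitude <- array(as.numeric(amplitude), dim = grid$n)
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    abort("field amplitude must be finite and non-negative")
  }
  structure(list(grid = grid, amplitude = amplitude), class = "field_volume")
}

#' @export
print.field_volume <- function(x, ...) {
  cat(sprintf("field_volume: %s voxels, peak |p| = %.4g\n",
              paste(x$grid$n, collapse = " x "), max(x$amplitude)))
  invisible(x)
}

#' Pressure-squared profile along a grid axis
#'
#' Samples |p|^2 along the axis-parallel line through the given physical
#' point (the other coordinates snap to the nearest voxel).
#'
#' @param field a [field_volume()].
#' @param axis axis to walk along (1 = x, 2 = y, 3 = z).
#' @param through physical coordinate the line passes through, meters (one
#'   entry per grid axis; the entry along `axis` is ignored).
#' @return a `beam_profile`: list with `x` (positions, m), `values` (|p|^2),
#'   `spacing` and `axis`.
#' @export
pressure_squared_profile <- function(field, axis, through) {
  stopifnot(inherits(field, "field_volume"))
  grid <- field$grid
  nd <- grid_ndim(grid)
  if (axis < 1 || axis > nd) abort("axis outside the grid")
  through <- rep_len(through, nd)
  fixed <- coord_to_index(grid, matrix(through, nrow = 1L))[1L, ]
  idx <- lapply(seq_len(nd), function(a) fixed[a])
  idx[[axis]] <- seq_len(grid$n[axis])
  vals <- do.call(`[`, c(list(field$amplitude), idx))^2
  structure(list(x = axis_coords(grid, axis), values = as.numeric(vals),
                 spacing = grid$dx, axis = axis),
            class = "beam_profile")
}

#' Full width at half maximum of a profile
#'
#' Finds the global maximum (first index on ties) and walks outward to the
#' first half-maximum crossings on each side, locating each crossing by
#' linear interpolation. With several lobes this returns the width of the
#' main lobe (the crossing pair closest to the peak).
#'
#' @param profile a `beam_profile`, or any list with numeric `x` and
#'   `values`.
#' @param peak optional position (in `x` units) of the lobe to measure;
#'   default is the profile's global maximum. Anchoring the search lets the
#'   caller measure the width of a known focal lobe even when a stronger
#'   feature (e.g. the field inside bone) lies elsewhere on the line.
#' @return width, in the units of `x` (meters for solver fields).
#' @export
fwhm <- function(profile, peak = NULL) {
  x <- profile$x
  y <- profile$values
  if (length(y) < 3L) abort("profile too short")
  if (all(y == 0)) abort("all-zero profile")
  ipk <- if (is.null(peak)) which.max(y) else which.min(abs(x - peak))
  if (ipk == 1L || ipk == length(y)) abort("profile peak lies on the boundary")
  half <- y[ipk] / 2
  cross <- function(side) {
    ii <- if (side < 0) seq(ipk, 1L) else seq(ipk, length(y))
    below <- which(y[ii] < half)
    if (!length(below)) {
      abort("profile does not fall below half maximum on one side")
    }
    j <- ii[below[1L]]          # first sample below half
    i <- j + ifelse(side < 0, 1L, -1L)  # neighbor still above
    x[i] + (x[j] - x[i]) * (y[i] - half) / (y[i] - y[j])
  }
  cross(+1) - cross(-1)
}

#' Focal position and deviation from a target
#'
#' `focal_position` returns the physical coordinate of the |p|^2 maximum
#' (ties resolved to the lowest linear index). `focal_deviation` compares it
#' with a target per axis and flags whether every axis deviation is within
#' the local FWHM of the pressure-squared profile through the peak -- the
#' acceptance notion used for targeting accuracy.
#'
#' @param field a [field_volume()].
#' @return `focal_position`: numeric coordinate vector (m).
#' @export
focal_position <- function(field) {
  stopifnot(inherits(field, "field_volume"))
  if (all(field$amplitude == 0)) abort("field is identically zero")
  lin <- which.max(field$amplitude)
  idx <- arrayInd(lin, field$grid$n)
  drop(index_to_coord(field$grid, idx))
}

#' @rdname focal_position
#' @param target physical target coordinate, meters.
#' @param search_region optional `list(lo =, hi = )` box (m): the focal
#'   peak is located inside this box (the scanned volume), while the
#'   half-maximum profiles through it are taken over the full field --
#'   mirroring a hydrophone protocol that finds the peak in a scan volume
#'   and then records longer line profiles through it.
#' @return `focal_deviation`: list with `position`, per-axis `deviation`
#'   (m), per-axis `fwhm` (m, NA on singleton axes), and `within_fwhm`.
#' @export
focal_deviation <- function(field, target, search_region = NULL) {
  pos <- if (is.null(search_region)) focal_position(field) else {
    focal_position(crop_field(field, search_region$lo, search_region$hi))
  }
  nd <- grid_ndim(field$grid)
  target <- rep_len(target, nd)
  dev <- abs(pos - target)
  widths <- rep(NA_real_, nd)
  for (a in seq_len(nd)) {
    if (field$grid$n[a] > 1L) {
      widths[a] <- fwhm(pressure_squared_profile(field, a, pos),
                        peak = if (!is.null(search_region)) pos[a])
    }
  }
  ok <- all(dev[!is.na(widths)] <= widths[!is.na(widths)])
  list(position = pos, deviation = dev, fwhm = widths, within_fwhm = ok)
}

#' Count distinct foci in a field
#'
#' Local maxima of |p|^2 above a threshold relative to the global peak,
#' merged when closer than `min_separation` (strongest survivor wins).
#' The threshold is in power dB: -6 dB keeps maxima whose |p|^2 exceeds
#' 10^(-0.6) of the peak (i.e. pressure amplitude above half the peak).
#'
#' @param field a [field_volume()].
#' @param threshold_db negative threshold relative to the peak, dB of
#'   |p|^2.
#' @param min_separation merge radius, meters.
#' @return list with `count` and `foci` (matrix of physical coordinates,
#'   strongest first).
#' @export
count_foci <- function(field, threshold_db = -6, min_separation) {
  stopifnot(inherits(field, "field_volume"))
  if (threshold_db >= 0) abort("threshold_db must be negative")
  p2 <- field$amplitude^2
  dims <- field$grid$n
  nd <- length(dims)
  is_max <- array(TRUE, dim = dims)
  for (a in which(dims > 1L)) {
    # strict on the +side, non-strict on the -side: plateaus yield one focus
    is_max <- is_max & (p2 > shift_axis(p2, a, by = 1L) |
                          seq_shield(dims, a, tail = TRUE)) &
      (p2 >= shift_axis(p2, a, by = -1L))
  }
  thr <- max(p2) * 10^(threshold_db / 10)
  cand <- which(is_max & p2 > thr)
  if (!length(cand)) return(list(count = 0L, foci = NULL))
  ord <- cand[order(p2[cand], decreasing = TRUE)]
  coords <- index_to_coord(field$grid, arrayInd(ord, dims))
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt(rowSums(sweep(coords[keep, , drop = FALSE], 2L,
                            coords[i, ], `-`)^2))
    if (all(d >= min_separation)) keep[i] <- TRUE
  }
  list(count = sum(keep), foci = coords[keep, , drop = FALSE])
}

# mask that is TRUE on the last slice along `axis` (boundary voxels keep
# their candidacy on the open side rather than comparing against the
# replicated edge)
seq_shield <- function(dims, axis, tail = TRUE) {
  m <- array(FALSE, dim = dims)
  idx <- lapply(dims, seq_len)
  idx[[axis]] <- if (tail) dims[axis] else 1L
  do.call(`[<-`, c(list(m), idx, list(value = TRUE)))
}

#' Intensity reflection coefficient at a plane interface
#'
#' `((Z1 - Z2) / (Z1 + Z2))^2` for normal incidence between media of
#' acoustic impedance `Z1` and `Z2`. The lens-design workflow reports this
#' as a diagnostic for the lens/coupling-layer interface (e.g. printed resin
#' against PDMS).
#'
#' @param Z1,Z2 acoustic impedances (any common unit, e.g. MRayl).
#' @return dimensionless intensity reflection coefficient in [0, 1).
#' @export
#' @examples
#' reflection_coefficient_intensity(3.03, 1.1)  # ~0.22
reflection_coefficient_intensity <- function(Z1, Z2) {
  check_positive_scalar(Z1, "Z1")
  check_positive_scalar(Z2, "Z2")
  ((Z1 - Z2) / (Z1 + Z2))^2
}
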