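# Simulation grids and acoustic material presets.

#' Construct a simulation grid
#'
#' Builds an isotropic voxel grid for the pseudospectral solver. The grid
#' must resolve the drive wavelength: pseudospectral collocation needs at
#' least two points per wavelength, so construction fails outright when
#' `dx >= c_min / (2 * f0)`.
#'
#' Voxel indices are 1-based (R convention); the physical coordinate of the
#' center of voxel `i` along an axis is `origin + (i - 1) * dx`. All lengths
#' are SI meters.
#'
#' @param extent physical length per axis, meters (length 1, 2 or 3).
#' @param dx isotropic grid spacing, meters.
#' @param f0 planned drive frequency, Hz.
#' @param c_min minimum sound speed anywhere in the medium, m/s.
#' @param origin physical coordinate of the center of voxel (1,1,1), meters.
#'   Defaults to 0 on every axis.
#' @return an object of class `sim_grid` with fields `n` (voxel counts),
#'   `dx`, and `origin`.
#' @export
#' @examples
#' g <- make_grid(extent = c(10e-3, 10e-3), dx = 0.1e-3,
#'                f0 = 2e6, c_min = 1482)
#' g$n  # 100 x 100
make_grid <- function(extent, dx, f0, c_min, origin = NULL) {
  if (!is.numeric(extent) || length(extent) < 1L || length(extent) > 3L ||
      any(!is.finite(extent)) || any(extent <= 0)) {
    abort("`extent` must be 1-3 positive physical lengths (meters)")
  }
  check_positive_scalar(dx, "dx")
  check_positive_scalar(f0, "f0")
  check_positive_scalar(c_min, "c_min")
  lim <- c_min / (2 * f0)
  if (dx >= lim) {
    abort(paste0("grid spacing dx = %.4g m does not resolve half the ",
                 "wavelength: need dx < c_min/(2 f0) = %.4g m"), dx, lim)
  }
  n <- as.integer(ceiling(extent / dx))
  origin <- origin %||% rep(0, length(n))
  if (length(origin) != length(n)) {
    abort("`origin` must have one coordinate per axis")
  }
  sim_grid(n, dx, origin)
}

#' Low-level sim_grid constructor
#'
#' @param n integer voxel counts per axis (length 1-3; trailing axes of
#'   count 1 are allowed and make the grid effectively lower-dimensional).
#' @param dx grid spacing, meters.
#' @param origin physical coordinate of the first voxel center, meters.
#' @return a `sim_grid` object.
#' @export
sim_grid <- function(n, dx, origin = rep(0, length(n))) {
  n <- as.integer(n)
  if (length(n) < 1L || length(n) > 3L || any(n < 1L)) {
    abort("voxel counts must be 1-3 integers, all >= 1")
  }
  check_positive_scalar(dx, "dx")
  structure(list(n = n, dx = dx, origin = as.numeric(origin)),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("sim_grid: %s voxels, dx = %.4g mm, origin = (%s) mm\n",
              paste(x$n, collapse = " x "), x$dx * 1e3,
              paste(sprintf("%.3g", x$origin * 1e3), collapse = ", ")))
  invisible(x)
}

# number of axes (singleton axes still count; derivatives on them vanish)
grid_ndim <- function(grid) length(grid$n)

# physical coordinates of voxel centers along one axis
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$n[axis]) - 1) * grid$dx
}

# physical coordinates (matrix) of an index matrix
index_to_coord <- function(grid, idx) {
  idx <- as.matrix(idx)
  sweep((idx - 1) * grid$dx, 2L, grid$origin, `+`)
}

# nearest voxel index matrix for physical coordinates
coord_to_index <- function(grid, coord) {
  coord <- matrix(coord, ncol = grid_ndim(grid))
  idx <- round(sweep(coord, 2L, grid$origin, `-`) / grid$dx) + 1
  storage.mode(idx) <- "integer"
  if (any(idx < 1L) || any(idx > rep(grid$n, each = nrow(idx)))) {
    abort("physical coordinate outside the grid")
  }
  idx
}

#' Define an acoustic material preset
#'
#' @param name label for the material.
#' @param rho0 density, kg/m^3.
#' @param c0 sound speed, m/s.
#' @param alpha0 power-law absorption coefficient, dB MHz^-gamma cm^-1.
#' @param gamma suggested power-law exponent when this material dominates a
#'   medium (the exponent is a single scalar per medium map).
#' @return a `material_preset` object (a named list).
#' @export
material_preset <- function(name, rho0, c0, alpha0 = 0, gamma = NA_real_) {
  check_positive_scalar(rho0, "rho0")
  check_positive_scalar(c0, "c0")
  if (!is.numeric(alpha0) || alpha0 < 0) abort("`alpha0` must be >= 0")
  structure(list(name = name, rho0 = rho0, c0 = c0, alpha0 = alpha0,
                 gamma = gamma),
            class = "material_preset")
}

#' Built-in material presets
#'
#' Literature defaults commonly used in transcranial ultrasound simulation.
#' They are explicit, documented stand-ins (the acoustic properties of real
#' skull bone vary with age and site) and every value can be overridden by
#' constructing a [material_preset()] directly.
#'
#' \describe{
#'   \item{water}{rho0 = 1000 kg/m^3, c0 = 1482 m/s,
#'     alpha0 = 0.0022 dB MHz^-2 cm^-1, gamma = 2.}
#'   \item{bone}{skull bone: rho0 = 1900 kg/m^3, c0 = 2800 m/s,
#'     alpha0 = 8 dB MHz^-1.1 cm^-1, gamma = 1.1.}
#'   \item{tissue}{soft tissue: rho0 = 1045 kg/m^3, c0 = 1540 m/s,
#'     alpha0 = 0.6 dB MHz^-1.1 cm^-1, gamma = 1.1.}
#' }
#'
#' @param name one of "water", "bone", "tissue"; omit for the full list.
#' @return a `material_preset`, or a named list of all presets.
#' @export
#' @examples
#' material_presets("bone")$c0
material_presets <- function(name = NULL) {
  presets <- list(
    water  = material_preset("water",  1000, 1482, 0.0022, 2),
    bone   = material_preset("bone",   1900, 2800, 8,      1.1),
    tissue = material_preset("tissue", 1045, 1540, 0.6,    1.1)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort("unknown preset '%s' (have: %s)", name,
          paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}
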