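# Conversion of a conjugated phase map into a printable lens thickness
# model, phase quantization, and STL geometry export.
#
# The lens imposes a position-dependent transmission phase by varying the
# thickness T(x, y) of lens material A against interfacing medium B:
#
#   dphi(x, y) = (k_B - k_A) (T0 - T(x, y))
#
# with k = 2 pi f0 / c the wavenumber in each medium and T0 the reference
# (maximum) thickness. Transmission is treated as one-dimensional
# propagation with a pure phase delay; internal multiple reflections are
# neglected in the design and only quantified as an interface diagnostic
# (see reflection_coefficient_intensity()).

#' Lens material pair
#'
#' @param c_A sound speed in the lens (printed) material, m/s. For a resin
#'   specified by impedance and density use `Z / rho` (e.g.
#'   3.03 MRayl / 1170 kg/m^3 = 2590 m/s).
#' @param c_B sound speed in the interfacing medium, m/s.
#' @param T0 reference thickness, m, or NULL to pick the thinnest thickness
#'   achieving full 2 pi coverage at the design frequency (T_min +
#'   2 pi / |k_B - k_A|, rounded up to 0.05 mm).
#' @param T_min minimum printable thickness, m.
#' @return a `lens_materials` object.
#' @export
lens_materials <- function(c_A, c_B, T0 = NULL, T_min = 0.2e-3) {
  check_positive_scalar(c_A, "c_A")
  check_positive_scalar(c_B, "c_B")
  if (c_A == c_B) abort("lens and interface media must have different speeds")
  if (T_min < 0) abort("T_min must be >= 0")
  if (!is.null(T0) && T0 <= T_min) abort("T0 must exceed T_min")
  structure(list(c_A = c_A, c_B = c_B, T0 = T0, T_min = T_min),
            class = "lens_materials")
}

#' Acoustic wavenumber
#'
#' @param c sound speed, m/s.
#' @param f0 frequency, Hz.
#' @return `2 pi f0 / c`, rad/m.
#' @export
#' @examples
#' wavenumber(1482, 1e6)  # ~4239.7 rad/m
wavenumber <- function(c, f0) {
  check_positive_scalar(c, "c")
  check_positive_scalar(f0, "f0")
  2 * pi * f0 / c
}

#' Convert a phase map to a lens thickness map
#'
#' Inverts the thin-lens phase relation: the target phase is wrapped into a
#' single 2 pi interval chosen so that `T` stays in
#' `(T0 - 2 pi / |k_B - k_A|, T0]`, then
#' `T(x, y) = T0 - wrap(dphi(x, y)) / (k_B - k_A)`. Construction fails if
#' the full 2 pi thickness span would push below `T_min`.
#'
#' @param map the (conjugated) `phase_map` to realize.
#' @param mats a [lens_materials()].
#' @param f0 design frequency, Hz; defaults to the map's.
#' @return a `thickness_map`: list with `T` (m, same layout as the map),
#'   `pitch`, `f0`, `T0`, and the materials.
#' @export
phase_to_thickness <- function(map, mats, f0 = NULL) {
  stopifnot(inherits(map, "phase_map"), inherits(mats, "lens_materials"))
  f0 <- f0 %||% map$f0
  dk <- wavenumber(mats$c_B, f0) - wavenumber(mats$c_A, f0)
  if (dk == 0) abort("k_B equals k_A: the lens cannot modulate phase")
  span <- 2 * pi / abs(dk)
  T0 <- mats$T0 %||% (ceiling((mats$T_min + span) / 0.05e-3) * 0.05e-3)
  if (T0 - span < mats$T_min) {
    abort(paste0("full 2 pi coverage spans %.3g mm but only %.3g mm sits ",
                 "between T0 and T_min"), span * 1e3,
          (T0 - mats$T_min) * 1e3)
  }
  w <- map$phase %% (2 * pi)          # [0, 2 pi)
  if (dk < 0) w <- w - 2 * pi         # (-2 pi, 0]
  T_ <- T0 - w / dk
  structure(list(T = T_, pitch = map$pitch, f0 = f0, T0 = T0,
                 T_min = mats$T_min, c_A = mats$c_A, c_B = mats$c_B),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  dims <- dim(x$T) %||% length(x$T)
  cat(sprintf("thickness_map: %s pixels, T in [%.3g, %.3g] mm, pitch %.3g mm\n",
              paste(dims, collapse = " x "), min(x$T) * 1e3, max(x$T) * 1e3,
              x$pitch * 1e3))
  invisible(x)
}

#' Quantize a phase map
#'
#' Rounds every phase to the nearest multiple of `step` (exact half-step
#' ties go to the lower level), then rewraps. The printer's discrete
#' layer/pixel resolution limits phase modulation to about 2 pi / 10, which
#' is the default step.
#'
#' @param map a `phase_map`.
#' @param step quantization step, radians in (0, 2 pi].
#' @return the quantized `phase_map`.
#' @export
quantize_phase <- function(map, step = 2 * pi / 10) {
  stopifnot(inherits(map, "phase_map"))
  if (step <= 0 || step > 2 * pi) abort("`step` must lie in (0, 2 pi]")
  q <- ceiling(map$phase / step - 0.5) * step   # half-ties to lower level
  map$phase <- wrap_phase(q)
  map
}

#' Build the lens solid as a triangle mesh
#'
#' Extrudes the thickness map into a watertight heightfield of square pixel
#' columns standing on a rectangular base plate. Units are millimeters
#' (printer convention).
#'
#' @param tmap a `thickness_map`.
#' @param base base plate thickness, m.
#' @return a `tri_mesh` in mm.
#' @export
thickness_mesh <- function(tmap, base = 0.5e-3) {
  Tm <- tmap$T
  if (is.null(dim(Tm))) Tm <- matrix(Tm, ncol = 1L)
  nx <- nrow(Tm); ny <- ncol(Tm)
  pitch <- tmap$pitch * 1e3              # mm
  h <- (Tm + base) * 1e3                 # column heights, mm
  xs <- (0:nx) * pitch
  ys <- (0:ny) * pitch
  quads <- list(); qi <- 0L
  quad <- function(p1, p2, p3, p4) {
    qi <<- qi + 1L
    quads[[qi]] <<- rbind(p1, p2, p3, p4)
  }
  # every wall is split at every distinct column height inside its span, so
  # vertical edges shared between walls subdivide identically everywhere
  # (no T-junctions) and the surface closes exactly
  levels_all <- sort(unique(as.vector(h)))
  # emit a vertical wall in the plane of edge (p_lo -> p_hi horizontal
  # span), from z = za to z = zb (za < zb), facing so that the quad order
  # (lo,za)(hi,za)(hi,zb)(lo,zb) when flip = FALSE; split at `levels`
  wall <- function(lo, hi, za, zb, levels, flip) {
    zsplit <- sort(unique(c(za, zb, levels[levels > za & levels < zb])))
    for (s in seq_len(length(zsplit) - 1L)) {
      z0 <- zsplit[s]; z1 <- zsplit[s + 1L]
      if (flip) {
        quad(c(lo, z0), c(lo, z1), c(hi, z1), c(hi, z0))
      } else {
        quad(c(lo, z0), c(hi, z0), c(hi, z1), c(lo, z1))
      }
    }
  }
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      x0 <- xs[i]; x1 <- xs[i + 1L]; y0 <- ys[j]; y1 <- ys[j + 1L]
      z <- h[i, j]
      # top (+z, CCW seen from above) and bottom (-z)
      quad(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z), c(x0, y1, z))
      quad(c(x0, y0, 0), c(x0, y1, 0), c(x1, y1, 0), c(x1, y0, 0))
      # walls live in (edge-coordinate, z) space: build as 2D then embed
      put_x <- function(Q) t(vapply(seq_len(4L), function(r)
        c(x1, Q[r, 1L], Q[r, 2L]), numeric(3L)))   # plane x = x1
      put_x0 <- function(Q) t(vapply(seq_len(4L), function(r)
        c(x0, Q[r, 1L], Q[r, 2L]), numeric(3L)))   # plane x = x0
      put_y <- function(Q) t(vapply(seq_len(4L), function(r)
        c(Q[r, 1L], y1, Q[r, 2L]), numeric(3L)))   # plane y = y1
      put_y0 <- function(Q) t(vapply(seq_len(4L), function(r)
        c(Q[r, 1L], y0, Q[r, 2L]), numeric(3L)))   # plane y = y0
      # +x wall (shared with (i+1, j), or outer boundary)
      zn <- if (i < nx) h[i + 1L, j] else 0
      if (z != zn) {
        before <- qi
        wall(y0, y1, min(z, zn), max(z, zn), levels_all, flip = (z < zn))
        for (q in (before + 1L):qi) quads[[q]] <- put_x(quads[[q]])
      }
      # -x outer boundary wall
      if (i == 1L && z > 0) {
        before <- qi
        wall(y0, y1, 0, z, levels_all, flip = TRUE)
        for (q in (before + 1L):qi) quads[[q]] <- put_x0(quads[[q]])
      }
      # +y wall
      zn <- if (j < ny) h[i, j + 1L] else 0
      if (z != zn) {
        before <- qi
        wall(x0, x1, min(z, zn), max(z, zn), levels_all, flip = (z > zn))
        for (q in (before + 1L):qi) quads[[q]] <- put_y(quads[[q]])
      }
      # -y outer boundary wall
      if (j == 1L && z > 0) {
        before <- qi
        wall(x0, x1, 0, z, levels_all, flip = FALSE)
        for (q in (before + 1L):qi) quads[[q]] <- put_y0(quads[[q]])
      }
    }
  }
  tri <- array(NA_real_, dim = c(2L * qi, 3L, 3L))
  for (q in seq_len(qi)) {
    Q <- quads[[q]]
    tri[2L * q - 1L, , ] <- Q[c(1L, 2L, 3L), ]
    tri[2L * q, , ] <- Q[c(1L, 3L, 4L), ]
  }
  mesh <- new_mesh(tri, "mm")
  if (mesh_volume(mesh) < 0) mesh$triangles <- tri[, c(1L, 3L, 2L), ]
  mesh
}

#' Export a thickness map as a printable STL
#'
#' Writes the [thickness_mesh()] solid to STL (binary by default), in
#' millimeters. The output is validated to be watertight before writing;
#' a non-watertight mesh is an error, never a warning.
#'
#' @param tmap a `thickness_map`.
#' @param path output STL path.
#' @param base base plate thickness, m.
#' @param format "binary" or "ascii".
#' @return `path`, invisibly.
#' @export
export_stl <- function(tmap, path, base = 0.5e-3,
                       format = c("binary", "ascii")) {
  mesh <- thickness_mesh(tmap, base = base)
  if (!mesh_is_watertight(mesh)) abort("exported lens mesh is not watertight")
  write_stl(mesh, path, format = match.arg(format))
  invisible(path)
}

#' Re-sample a lens mesh back into per-pixel thickness
#'
#' Casts a vertical ray at every pixel center and takes the highest surface
#' intersection, returning `T = z_top - base`. Used to confirm that an
#' exported mesh reproduces the designed thickness map.
#'
#' @param mesh a `tri_mesh` in mm (e.g. from [read_stl()]).
#' @param pitch pixel pitch, m.
#' @param dims pixel counts c(nx, ny).
#' @param base base plate thickness, m.
#' @return thickness matrix, m.
#' @export
resample_heightfield <- function(mesh, pitch, dims, base = 0.5e-3) {
  pitch_mm <- pitch * 1e3
  cx <- (seq_len(dims[1L]) - 0.5) * pitch_mm
  cy <- (seq_len(dims[2L]) - 0.5) * pitch_mm
  pts <- as.matrix(expand.grid(x = cx, y = cy))
  hits <- ray_z_hits(mesh, pts)
  top <- vapply(hits, function(z) if (length(z)) max(z) else NA_real_,
                numeric(1L))
  matrix(top / 1e3 - base, nrow = dims[1L])
}
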