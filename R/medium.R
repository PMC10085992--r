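# Voxelized acoustic property maps.

#' Construct a medium map
#'
#' A `medium_map` holds per-voxel density, sound speed and power-law
#' absorption over a [sim_grid()], plus the (scalar) power-law exponent
#' shared by all voxels. Validity: all densities and speeds strictly
#' positive, absorption non-negative, and `1 < gamma < 3` whenever any voxel
#' absorbs (outside that range the fractional-Laplacian absorption operator
#' is ill-defined).
#'
#' @param grid a `sim_grid`.
#' @param rho0 density per voxel, kg/m^3 (array of dim `grid$n`, or scalar).
#' @param c0 sound speed per voxel, m/s (array or scalar).
#' @param alpha0 absorption per voxel, dB MHz^-gamma cm^-1 (array or scalar).
#' @param gamma scalar power-law exponent.
#' @return a `medium_map` object.
#' @export
medium_map <- function(grid, rho0, c0, alpha0 = 0, gamma = 1.5) {
  stopifnot(inherits(grid, "sim_grid"))
  expand <- function(x, name) {
    if (length(x) == 1L) x <- array(x, dim = grid$n)
    dx <- dim(x) %||% length(x)
    if (!identical(as.integer(dx), grid$n)) {
      abort("`%s` does not match the grid dimensions", name)
    }
    array(as.numeric(x), dim = grid$n)
  }
  rho0 <- expand(rho0, "rho0")
  c0 <- expand(c0, "c0")
  alpha0 <- expand(alpha0, "alpha0")
  if (any(!is.finite(rho0)) || any(rho0 <= 0)) abort("rho0 must be > 0")
  if (any(!is.finite(c0)) || any(c0 <= 0)) abort("c0 must be > 0")
  if (any(!is.finite(alpha0)) || any(alpha0 < 0)) abort("alpha0 must be >= 0")
  if (any(alpha0 > 0) && (gamma <= 1 || gamma >= 3)) {
    abort("gamma must lie in (1, 3) when the medium absorbs (got %.3g)", gamma)
  }
  structure(list(grid = grid, rho0 = rho0, c0 = c0, alpha0 = alpha0,
                 gamma = gamma),
            class = "medium_map")
}

#' @export
print.medium_map <- function(x, ...) {
  cat(sprintf(paste0("medium_map on %s grid: c0 in [%.0f, %.0f] m/s, ",
                     "rho0 in [%.0f, %.0f] kg/m^3, max alpha0 %.3g dB ",
                     "MHz^-%.2g cm^-1\n"),
              paste(x$grid$n, collapse = "x"), min(x$c0), max(x$c0),
              min(x$rho0), max(x$rho0), max(x$alpha0), x$gamma))
  invisible(x)
}

#' Homogeneous medium from a preset
#'
#' @param grid a `sim_grid`.
#' @param mat a [material_preset()].
#' @param gamma power-law exponent; defaults to the preset's suggestion
#'   (or 1.5 if the preset has none).
#' @return a `medium_map`.
#' @export
homogeneous_medium <- function(grid, mat = material_presets("water"),
                               gamma = NULL) {
  gamma <- gamma %||% (if (is.finite(mat$gamma)) mat$gamma else 1.5)
  medium_map(grid, mat$rho0, mat$c0, mat$alpha0, gamma)
}

#' Synthetic ellipsoidal skull-like shell
#'
#' Builds a skull-like aberrator as the region between two concentric
#' ellipsoids: the outer surface has the given semi-axes and the inner
#' surface has each semi-axis reduced by `thickness`. Voxel centers whose
#' normalized inner radius is >= 1 and normalized outer radius is <= 1 get
#' the shell material; voxels inside the inner surface get `inner`; the
#' rest get `outer`. The construction is deterministic.
#'
#' This is a parametric stand-in for a CT-derived skull mesh: it reproduces
#' the aberrating features that matter for time-reversal focusing (curved
#' high-speed, high-density bone layer of finite thickness) without the
#' anatomy.
#'
#' @param grid a `sim_grid`.
#' @param center ellipsoid center, physical coordinates (m), one per axis.
#' @param semi_axes outer semi-axes (m), one per axis. Axes whose grid count
#'   is 1 are ignored (2D shells from a 3D parameterization).
#' @param thickness shell thickness (m), subtracted from every semi-axis to
#'   form the inner surface; 0 gives a degenerate (empty) shell.
#' @param inner,shell_mat,outer [material_preset()]s for the cavity, the
#'   shell, and the exterior.
#' @param gamma power-law exponent for the whole map; defaults to the shell
#'   material's suggestion.
#' @param cap optionally keep only half of the shell: `list(axis =, sign =)`
#'   retains shell voxels on the `sign` (+1/-1) side of the center along
#'   `axis`. This emulates the excised half-skull used when a hydrophone
#'   must reach the cavity, and avoids closed-cavity reverberation.
#' @param thickness_mod optional sinusoidal thickness modulation,
#'   `list(amplitude =, period =, axis =)` (m, m, axis index): the local
#'   shell thickness becomes
#'   `thickness + amplitude * sin(2 pi (coord - center) / period)`. A
#'   smooth uniform shell is only a low-order aberrator (it mainly
#'   defocuses); modulation reproduces the suture/thickness variability of
#'   real skulls that scrambles an uncorrected focus.
#' @return a `medium_map`.
#' @export
synthetic_skull_shell <- function(grid, center, semi_axes, thickness,
                                  inner = material_presets("water"),
                                  shell_mat = material_presets("bone"),
                                  outer = material_presets("water"),
                                  gamma = NULL, cap = NULL,
                                  thickness_mod = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  nd <- grid_ndim(grid)
  if (length(center) != nd || length(semi_axes) != nd) {
    abort("`center` and `semi_axes` need one entry per grid axis")
  }
  if (thickness < 0) abort("`thickness` must be >= 0")
  if (any(semi_axes <= 0)) abort("semi-axes must be > 0")
  active <- grid$n > 1L
  lo <- grid$origin
  hi <- grid$origin + (grid$n - 1) * grid$dx
  if (any((center - semi_axes)[active] < lo[active]) ||
      any((center + semi_axes)[active] > hi[active])) {
    abort("shell exceeds the grid bounds")
  }
  inner_axes <- pmax(semi_axes - thickness, 0)

  # normalized radius fields (squared), computed axis-by-axis by broadcasting
  norm_r2 <- function(axes) {
    acc <- array(0, dim = grid$n)
    for (a in seq_len(nd)) {
      if (!active[a]) next
      u <- (axis_coords(grid, a) - center[a]) / axes[a]
      shape <- rep(1L, nd); shape[a] <- grid$n[a]
      acc <- acc + array(rep(u^2, each = prod(grid$n[seq_len(a - 1L)])),
                         dim = grid$n)
    }
    acc
  }
  # normalized radius against per-voxel inner semi-axes (thickness may be
  # modulated along one axis)
  norm_r2_var <- function(t_arr) {
    acc <- array(0, dim = grid$n)
    for (a in seq_len(nd)) {
      if (!active[a]) next
      u <- axis_array(axis_coords(grid, a) - center[a], a, grid$n)
      ax <- pmax(semi_axes[a] - t_arr, grid$dx / 100)
      acc <- acc + (u / ax)^2
    }
    acc
  }
  r2_out <- norm_r2(semi_axes)
  inside_outer <- r2_out <= 1
  if (thickness == 0 || any(inner_axes == 0)) {
    in_shell <- array(FALSE, dim = grid$n)
    inside_inner <- inside_outer
  } else if (is.null(thickness_mod)) {
    r2_in <- norm_r2(inner_axes)
    inside_inner <- r2_in < 1
    in_shell <- inside_outer & !inside_inner
  } else {
    tm <- thickness_mod
    t_prof <- thickness + tm$amplitude *
      sin(2 * pi * (axis_coords(grid, tm$axis) - center[tm$axis]) /
            tm$period)
    t_arr <- axis_array(t_prof, tm$axis, grid$n)
    r2_in <- norm_r2_var(t_arr)
    inside_inner <- r2_in < 1
    in_shell <- inside_outer & !inside_inner
  }
  if (!is.null(cap)) {
    side <- (axis_coords(grid, cap$axis) - center[cap$axis]) * cap$sign >= 0
    keep <- axis_array(side, cap$axis, grid$n)
    in_shell <- in_shell & keep
  }

  pick <- function(field) {
    out <- array(outer[[field]], dim = grid$n)
    out[inside_inner] <- inner[[field]]
    out[in_shell] <- shell_mat[[field]]
    out
  }
  gamma <- gamma %||% (if (is.finite(shell_mat$gamma)) shell_mat$gamma else 1.5)
  m <- medium_map(grid, pick("rho0"), pick("c0"), pick("alpha0"), gamma)
  m$shell_mask <- in_shell
  m
}

#' Save / load package containers
#'
#' Medium maps, sensor records, phase maps, thickness maps and field volumes
#' are serialized with R's native RDS format; spectra and trajectories use
#' CSV, configs YAML/JSON.
#'
#' @param x object to save.
#' @param path file path.
#' @return `read_container` returns the object; `save_container` returns
#'   `path` invisibly.
#' @export
save_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_container
#' @export
read_container <- function(path) readRDS(path)
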