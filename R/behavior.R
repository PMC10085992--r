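# Open-field trajectory analytics: speed, cumulative distance, Gaussian
# occupancy maps. Trajectories arrive as already-tracked per-frame
# coordinates (e.g. pose-tracker exports).

#' Construct a trajectory
#'
#' @param times frame times, seconds (strictly increasing).
#' @param x,y positions per frame, cm (arena frame).
#' @param confidence optional per-frame tracker confidence.
#' @return a `trajectory` object.
#' @export
trajectory <- function(times, x, y, confidence = NULL) {
  if (length(times) < 2L) abort("a trajectory needs at least 2 frames")
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  if (length(x) != length(times) || length(y) != length(times)) {
    abort("times, x and y must have equal length")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("coordinates must be finite")
  }
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), confidence = confidence),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames over %.3g s, %.3g cm travelled\n",
              length(x$times), diff(range(x$times)), cumulative_distance(x)))
  invisible(x)
}

#' Average speed
#'
#' Sum of per-frame Euclidean step lengths divided by the total elapsed
#' time; by construction `average_speed * elapsed == cumulative_distance`.
#'
#' @param traj a [trajectory()].
#' @return cm/s.
#' @export
average_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  cumulative_distance(traj) / (traj$times[length(traj$times)] - traj$times[1L])
}

#' Cumulative travel distance
#'
#' Path length: the sum of per-frame displacements (not the net
#' displacement).
#'
#' @param traj a [trajectory()].
#' @return cm.
#' @export
cumulative_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Arena grid for occupancy maps
#'
#' @param xlim,ylim arena extents, cm.
#' @param pitch pixel pitch, cm (default 0.5, half the occupancy kernel
#'   sigma).
#' @return an `arena_grid` object.
#' @export
arena_grid <- function(xlim, ylim, pitch = 0.5) {
  check_positive_scalar(pitch, "pitch")
  if (diff(xlim) <= 0 || diff(ylim) <= 0) abort("arena extents must be positive")
  structure(list(xlim = xlim, ylim = ylim, pitch = pitch,
                 xc = seq(xlim[1L] + pitch / 2, xlim[2L], by = pitch),
                 yc = seq(ylim[1L] + pitch / 2, ylim[2L], by = pitch)),
            class = "arena_grid")
}

#' Gaussian occupancy map
#'
#' For every frame, each arena pixel at offset `(dx, dy)` from the animal
#' accrues the weight `exp(-(dx^2 + dy^2) / (2 sigma^2))`; per-frame maps
#' are summed over frames. Frames outside the arena are dropped (their
#' count is attached as the `n_clipped` attribute and a warning is raised).
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_grid()].
#' @param sigma Gaussian kernel width, cm (default 1).
#' @return an `occupancy_map`: list with `values` (nx x ny matrix), the
#'   arena, and `sigma`.
#' @export
occupancy_map <- function(traj, arena, sigma = 1) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_grid"))
  check_positive_scalar(sigma, "sigma")
  inside <- traj$x >= arena$xlim[1L] & traj$x <= arena$xlim[2L] &
    traj$y >= arena$ylim[1L] & traj$y <= arena$ylim[2L]
  n_clipped <- sum(!inside)
  if (n_clipped > 0L) {
    warning(sprintf("%d frames outside the arena were dropped", n_clipped))
  }
  vals <- matrix(0, length(arena$xc), length(arena$yc))
  for (i in which(inside)) {
    wx <- exp(-(arena$xc - traj$x[i])^2 / (2 * sigma^2))
    wy <- exp(-(arena$yc - traj$y[i])^2 / (2 * sigma^2))
    vals <- vals + outer(wx, wy)   # separable 2D Gaussian
  }
  structure(list(values = vals, arena = arena, sigma = sigma,
                 n_clipped = n_clipped),
            class = "occupancy_map")
}

#' Total occupancy
#'
#' Sum of the occupancy map over all pixels (dimensionless weight sum;
#' multiply by `pitch^2` for the spatial integral in cm^2). For a single
#' frame on a fine grid this approaches `2 pi sigma^2 / pitch^2`.
#'
#' @param map an [occupancy_map()].
#' @return scalar.
#' @export
total_occupancy <- function(map) {
  stopifnot(inherits(map, "occupancy_map"))
  sum(map$values)
}

#' Load a tracked trajectory from CSV
#'
#' Expects columns `frame`, `x`, `y` and optionally `confidence`. Pixel (or
#' other raw) coordinates are converted to cm by `scale`; frames below
#' `min_confidence` are dropped and re-filled by linear interpolation when
#' the gap is at most `max_gap` frames (longer gaps are an error).
#'
#' @param path CSV path.
#' @param frame_rate frames per second.
#' @param scale cm per raw coordinate unit.
#' @param min_confidence confidence threshold (NULL = keep everything).
#' @param max_gap longest interpolatable run of dropped frames.
#' @return a [trajectory()].
#' @export
load_trajectory <- function(path, frame_rate, scale = 1,
                            min_confidence = NULL, max_gap = 5L) {
  d <- read.csv(path)
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort("trajectory CSV is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (any(diff(d$frame) <= 0)) abort("frame numbers must be increasing")
  x <- d$x * scale
  y <- d$y * scale
  if (!is.null(min_confidence) && "confidence" %in% names(d)) {
    bad <- d$confidence < min_confidence
    if (any(bad)) {
      runs <- rle(bad)
      if (any(runs$lengths[runs$values] > max_gap)) {
        abort("low-confidence gap longer than %d frames", max_gap)
      }
      if (bad[1L] || bad[length(bad)]) {
        abort("cannot interpolate low-confidence frames at the trajectory ends")
      }
      x[bad] <- approx(d$frame[!bad], x[!bad], xout = d$frame[bad])$y
      y[bad] <- approx(d$frame[!bad], y[!bad], xout = d$frame[bad])$y
    }
  }
  trajectory(times = d$frame / frame_rate, x = x, y = y,
             confidence = if ("confidence" %in% names(d)) d$confidence)
}

#' Synthetic bounded correlated random walk
#'
#' Fixture generator emulating open-field locomotion: Gaussian steps with
#' first-order directional persistence, reflected at the arena walls.
#' Fully reproducible given the seed.
#'
#' @param n_frames number of frames.
#' @param frame_rate frames per second.
#' @param arena an [arena_grid()] (bounds only).
#' @param step_sigma per-axis step standard deviation, cm/frame.
#' @param persistence AR(1) coefficient in [0, 1) of the step process.
#' @param seed RNG seed.
#' @param start start position, cm (default arena center).
#' @return a [trajectory()].
#' @export
synthetic_trajectory <- function(n_frames, frame_rate, arena,
                                 step_sigma = 0.5, persistence = 0,
                                 seed = 1L, start = NULL) {
  stopifnot(inherits(arena, "arena_grid"))
  if (persistence < 0 || persistence >= 1) {
    abort("persistence must lie in [0, 1)")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  start <- start %||% c(mean(arena$xlim), mean(arena$ylim))
  innov <- step_sigma * sqrt(1 - persistence^2)
  sx <- sy <- 0
  x <- y <- numeric(n_frames)
  x[1L] <- start[1L]; y[1L] <- start[2L]
  reflect <- function(p, lim) {
    while (p < lim[1L] || p > lim[2L]) {
      if (p < lim[1L]) p <- 2 * lim[1L] - p
      if (p > lim[2L]) p <- 2 * lim[2L] - p
    }
    p
  }
  for (i in seq_len(n_frames - 1L)) {
    sx <- persistence * sx + innov * rnorm(1L)
    sy <- persistence * sy + innov * rnorm(1L)
    x[i + 1L] <- reflect(x[i] + sx, arena$xlim)
    y[i + 1L] <- reflect(y[i] + sy, arena$ylim)
  }
  trajectory(times = (seq_len(n_frames) - 1L) / frame_rate, x = x, y = y)
}
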