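# k-space pseudospectral time-domain solver for linear acoustics in
# heterogeneous power-law absorbing media.
#
# The scheme advances the coupled first-order system (mass conservation,
# momentum conservation, absorbing pressure-density relation) with Fourier
# collocation derivatives on spatially staggered grids, the k-space temporal
# correction factor sinc(c_ref k dt / 2), a split-field perfectly matched
# layer at the grid edges, and the power-law absorption operator applied as
# two fractional-Laplacian k-space corrections (dispersion + absorption).
# Heterogeneous density enters through the staggered-density momentum update
# and the density-gradient correction implicit in the split mass-conservation
# update; this is the standard equivalent of the particle-displacement
# heterogeneity term in the pressure-density relation.

#' Compute the solver time step
#'
#' `dt = cfl * dx / c_max`, then reduced to the nearest value such that the
#' drive period `1/f0` is an exact integer multiple of `dt`. The exact
#' divisibility makes steady-state quadrature demodulation at `f0`
#' orthogonal over whole periods.
#'
#' @param cfl Courant-Friedrichs-Lewy number in (0, 1]; 0.3 is the package
#'   default throughout.
#' @param dx grid spacing, m.
#' @param c_max maximum sound speed in the medium, m/s.
#' @param f0 drive frequency, Hz, or NULL to skip the divisor adjustment.
#' @return time step, seconds.
#' @export
#' @examples
#' compute_dt(0.3, 1e-4, 3000, 2e6)  # 1e-8 s (period = 50 dt)
compute_dt <- function(cfl, dx, c_max, f0 = NULL) {
  if (!is.numeric(cfl) || length(cfl) != 1L || cfl <= 0 || cfl > 1) {
    abort("`cfl` must lie in (0, 1]")
  }
  check_positive_scalar(dx, "dx")
  check_positive_scalar(c_max, "c_max")
  dt <- cfl * dx / c_max
  if (!is.null(f0)) {
    check_positive_scalar(f0, "f0")
    period <- 1 / f0
    dt <- period / ceiling(period / dt)
  }
  dt
}

#' Define an acoustic source
#'
#' Sources inject pressure additively at one or more voxels, so
#' superposition holds exactly (required for multifocus time-reversal
#' recording). Either give an explicit `waveform` (Pa, one column per
#' position or a single shared column), or give `f0` for monochromatic
#' drive `amplitude * sin(2 pi f0 t + phase)` built once the time step is
#' known. Monochromatic sources ramp up over `ramp_cycles` cycles to limit
#' broadband switch-on transients.
#'
#' @param positions voxel index matrix (rows = positions, cols = axes) or a
#'   single index vector.
#' @param waveform numeric vector or matrix of pressure samples, Pa.
#' @param f0 drive frequency, Hz (monochromatic mode).
#' @param amplitude scalar or per-position drive amplitudes, Pa.
#' @param phase scalar or per-position phase offsets, radians.
#' @param ramp_cycles cosine-tapered onset length, drive cycles.
#' @return a `source_spec` object.
#' @export
source_spec <- function(positions, waveform = NULL, f0 = NULL,
                        amplitude = 1, phase = 0, ramp_cycles = 2) {
  positions <- if (is.matrix(positions)) positions else matrix(positions, nrow = 1L)
  if (is.null(waveform) && is.null(f0)) {
    abort("give either an explicit `waveform` or a drive frequency `f0`")
  }
  if (!is.null(waveform) && any(!is.finite(waveform))) {
    abort("waveform must be finite")
  }
  np <- nrow(positions)
  structure(list(positions = positions, waveform = waveform, f0 = f0,
                 amplitude = rep_len(amplitude, np),
                 phase = rep_len(phase, np),
                 ramp_cycles = ramp_cycles),
            class = "source_spec")
}

#' Absorbing-boundary configuration
#'
#' @param type "pml" (split-field perfectly matched layer) or "periodic"
#'   (no absorption; waves wrap around).
#' @param size layer thickness, voxels.
#' @param order polynomial grading order of the absorption profile.
#' @param target_reflection design plane-wave reflection coefficient.
#' @return a boundary configuration list.
#' @export
boundary_spec <- function(type = c("pml", "periodic"), size = 10L,
                          order = 4, target_reflection = 1e-4) {
  list(type = match.arg(type), size = as.integer(size), order = order,
       target_reflection = target_reflection)
}

# wavenumber vector for one axis (rad/m), FFT ordering
kvec <- function(n, dx) {
  if (n == 1L) return(0)
  i <- 0:(n - 1L)
  f <- ifelse(i <= n %/% 2, i, i - n)
  2 * pi * f / (n * dx)
}

# broadcast a per-axis vector into an array of dim `dims`
axis_array <- function(v, axis, dims) {
  array(rep(v, each = prod(dims[seq_len(axis - 1L)])), dim = dims)
}

# shift an array by one voxel along `axis` (edge replicated)
shift_axis <- function(x, axis, by = 1L) {
  dims <- dim(x) %||% length(x)
  idx <- lapply(dims, seq_len)
  src <- pmin(pmax(idx[[axis]] + by, 1L), dims[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftn <- function(x) fft(x, inverse = TRUE) / length(x)

# one-axis PML attenuation factors exp(-sigma dt / 2) at regular and
# staggered (+dx/2) points
pml_profiles <- function(n, dx, dt, c_ref, bnd) {
  ones <- rep(1, n)
  if (bnd$type != "pml" || n == 1L) return(list(reg = ones, sg = ones))
  L <- bnd$size
  if (2L * L >= n) abort("grid too small for a %d-voxel PML on both ends", L)
  sigma_max <- -(bnd$order + 1) * c_ref * log(bnd$target_reflection) /
    (2 * L * dx)
  prof <- function(pos) { # pos: voxel-center position (may be half-integer)
    xl <- (L + 1 - pos) / L           # depth fraction into left layer
    xr <- (pos - (n - L)) / L         # depth fraction into right layer
    x <- pmax(0, pmax(xl, xr))
    x <- pmin(x, 1)
    exp(-sigma_max * x^bnd$order * dt / 2)
  }
  list(reg = prof(seq_len(n)), sg = prof(seq_len(n) + 0.5))
}

# Core stepper. `sensors_lin` are linear indices to record; `demod` is
# NULL or list(f0, n_steps) requesting in-place quadrature accumulation
# over the last n_steps steps; `track_energy` accumulates the total
# acoustic energy (compressional + kinetic) each step.
sim_core <- function(medium, sources, dt, nt, boundary, sensors_lin = NULL,
                     demod = NULL, track_energy = FALSE) {
  grid <- medium$grid
  dims <- grid$n
  nd <- length(dims)
  active <- which(dims > 1L)
  dx <- grid$dx
  c_ref <- max(medium$c0)

  # spectral operators
  K <- lapply(seq_len(nd), function(a) axis_array(kvec(dims[a], dx), a, dims))
  kmag2 <- Reduce(`+`, lapply(K, function(k) k^2))
  kappa <- sinc(c_ref * sqrt(kmag2) * dt / 2)
  Dpos <- Dneg <- vector("list", nd)
  for (a in active) {
    Dpos[[a]] <- 1i * K[[a]] * kappa * exp(+1i * K[[a]] * dx / 2)
    Dneg[[a]] <- 1i * K[[a]] * kappa * exp(-1i * K[[a]] * dx / 2)
  }

  # staggered density and PML factors
  rho0_sg <- lapply(seq_len(nd), function(a) {
    if (a %in% active) (medium$rho0 + shift_axis(medium$rho0, a)) / 2
    else medium$rho0
  })
  pml_u <- pml_r <- vector("list", nd)
  for (a in active) {
    pr <- pml_profiles(dims[a], dx, dt, c_ref, boundary)
    pml_r[[a]] <- axis_array(pr$reg, a, dims)
    pml_u[[a]] <- axis_array(pr$sg, a, dims)
  }

  # absorption operators (power law)
  absorbing <- any(medium$alpha0 > 0)
  if (absorbing) {
    gamma <- medium$gamma
    alpha_np <- db_to_neper(medium$alpha0, gamma)
    tau <- -2 * alpha_np * medium$c0^(gamma - 1)
    eta <- 2 * alpha_np * medium$c0^gamma * tan(pi * gamma / 2)
    kmag <- sqrt(kmag2)
    nabla1 <- kmag^(gamma - 2)
    nabla1[kmag == 0] <- 0
    nabla2 <- kmag^(gamma - 1)
    nabla2[kmag == 0] <- 0
  }

  # source bookkeeping
  src_lin <- linear_index(sources$positions, dims)
  c0sq_src <- medium$c0[src_lin]^2
  n_act <- length(active)
  t_vec <- (seq_len(nt)) * dt
  if (is.null(sources$waveform)) {
    f0 <- sources$f0
    env <- pmin(1, t_vec * f0 / max(sources$ramp_cycles, 1e-12))
    if (sources$ramp_cycles == 0) env <- rep(1, nt)
    wf <- outer(t_vec, sources$phase, function(t, ph) sin(2 * pi * f0 * t + ph))
    wf <- wf * env
    wf <- sweep(wf, 2L, sources$amplitude, `*`)
  } else {
    wf <- sources$waveform
    if (is.null(dim(wf))) wf <- matrix(wf, ncol = 1L)
    if (ncol(wf) == 1L && length(src_lin) > 1L) {
      wf <- wf[, rep(1L, length(src_lin)), drop = FALSE]
    }
    if (nrow(wf) < nt) {
      wf <- rbind(wf, matrix(0, nt - nrow(wf), ncol(wf)))
    }
    wf <- sweep(wf, 2L, sources$amplitude, `*`)
  }

  # state
  zero <- array(0, dim = dims)
  u <- rho <- du <- vector("list", nd)
  for (a in active) { u[[a]] <- zero; rho[[a]] <- zero }
  p <- zero
  rec <- if (!is.null(sensors_lin)) {
    matrix(0, nrow = nt, ncol = length(sensors_lin))
  }
  energy <- if (track_energy) numeric(nt)
  if (!is.null(demod)) {
    Ic <- Is <- zero
    w0 <- 2 * pi * demod$f0
    demod_start <- nt - demod$n_steps + 1L
  }

  for (n in seq_len(nt)) {
    p_k <- fft(p)
    for (a in active) {
      dpdx <- Re(ifftn(Dpos[[a]] * p_k))
      u[[a]] <- pml_u[[a]] * (pml_u[[a]] * u[[a]] - (dt / rho0_sg[[a]]) * dpdx)
    }
    for (a in active) {
      du[[a]] <- Re(ifftn(Dneg[[a]] * fft(u[[a]])))
      rho[[a]] <- pml_r[[a]] * (pml_r[[a]] * rho[[a]] -
                                  dt * medium$rho0 * du[[a]])
    }
    # additive pressure injection, split across the density components
    s_n <- wf[n, ] / (c0sq_src * n_act)
    for (a in active) rho[[a]][src_lin] <- rho[[a]][src_lin] + s_n
    rho_sum <- Reduce(`+`, rho[active])
    if (absorbing) {
      div_u <- Reduce(`+`, du[active])
      p <- medium$c0^2 * (rho_sum +
        tau * Re(ifftn(nabla1 * fft(medium$rho0 * div_u))) -
        eta * Re(ifftn(nabla2 * fft(rho_sum))))
    } else {
      p <- medium$c0^2 * rho_sum
    }
    if (!is.null(rec)) rec[n, ] <- p[sensors_lin]
    if (track_energy) {
      e <- sum(p^2 / (2 * medium$rho0 * medium$c0^2))
      for (a in active) e <- e + sum(rho0_sg[[a]] * u[[a]]^2) / 2
      energy[n] <- e
    }
    if (!is.null(demod) && n >= demod_start) {
      wt <- w0 * t_vec[n]
      Ic <- Ic + p * cos(wt)
      Is <- Is + p * sin(wt)
    }
    if (n %% 100L == 0L && !is.finite(p[[1L]] + sum(p[src_lin]))) {
      abort("solver instability: non-finite pressure at step %d (t = %.3g s)",
            n, t_vec[n])
    }
  }
  if (any(!is.finite(p))) {
    abort("solver instability: non-finite pressure at the final step")
  }

  out <- list(dt = dt, nt = nt)
  if (track_energy) out$energy <- energy
  if (!is.null(rec)) out$pressures <- rec
  if (!is.null(demod)) {
    half_n <- demod$n_steps / 2
    out$amplitude <- sqrt(Ic^2 + Is^2) / half_n
    out$phase <- atan2(Ic, Is)   # p ~ A sin(w t + phase)
  }
  out
}

#' Run a time-domain acoustic simulation
#'
#' Advances the first-order acoustic equations with spectral (Fourier
#' collocation) spatial derivatives, the k-space temporal correction
#' `sinc(c_ref k dt / 2)` (with `c_ref` the maximum sound speed), power-law
#' absorption whenever any voxel has `alpha0 > 0`, and an absorbing
#' perfectly-matched layer at the grid edges. Returns the pressure trace at
#' every sensor position.
#'
#' @param medium a [medium_map()].
#' @param sources a [source_spec()].
#' @param sensors voxel index matrix (rows = sensors).
#' @param duration simulated time, seconds. For steady-state phase recording
#'   drive at least 20 cycles plus the propagation time.
#' @param cfl CFL number, default 0.3.
#' @param boundary a [boundary_spec()].
#' @param f0 frequency used to adjust `dt` so one period is an integer
#'   number of steps; defaults to the source's `f0` if monochromatic.
#' @param track_energy if TRUE, the total acoustic energy (compressional +
#'   kinetic, arbitrary units) is recorded each step into `$energy`.
#' @return a `sensor_record`: list with `positions`, `dt`, `t0` (time of the
#'   first sample), and `pressures` (time x sensor matrix, Pa).
#' @export
run_simulation <- function(medium, sources, sensors, duration, cfl = 0.3,
                           boundary = boundary_spec(), f0 = NULL,
                           track_energy = FALSE) {
  stopifnot(inherits(medium, "medium_map"), inherits(sources, "source_spec"))
  sensors <- if (is.matrix(sensors)) sensors else matrix(sensors, nrow = 1L)
  f0 <- f0 %||% sources$f0
  dt <- compute_dt(cfl, medium$grid$dx, max(medium$c0), f0)
  nt <- max(1L, round(duration / dt))
  sens_lin <- linear_index(sensors, medium$grid$n)
  res <- sim_core(medium, sources, dt, nt, boundary, sensors_lin = sens_lin,
                  track_energy = track_energy)
  structure(list(positions = sensors, dt = dt, t0 = dt,
                 pressures = res$pressures, energy = res$energy),
            class = "sensor_record")
}

#' @export
print.sensor_record <- function(x, ...) {
  cat(sprintf("sensor_record: %d sensors x %d samples, dt = %.4g s\n",
              ncol(x$pressures), nrow(x$pressures), x$dt))
  invisible(x)
}

#' Steady-state monochromatic field over the whole grid
#'
#' Drives the sources for `n_cycles` cycles of `f0` (plus, optionally, extra
#' propagation time) and demodulates the pressure at every voxel over the
#' final `integrate_cycles` full periods, returning amplitude and phase
#' fields. The phase convention is `p ~ A sin(2 pi f0 t + phase)` with `t`
#' measured from the source switch-on.
#'
#' @param medium a [medium_map()].
#' @param sources a [source_spec()] (monochromatic).
#' @param f0 drive frequency, Hz.
#' @param n_cycles total number of drive cycles to simulate.
#' @param integrate_cycles number of final periods in the demodulation
#'   window.
#' @param cfl,boundary solver controls, see [run_simulation()].
#' @return list with `amplitude` and `phase` arrays (dim = grid), plus `dt`.
#' @export
steady_state_field <- function(medium, sources, f0, n_cycles = 20,
                               integrate_cycles = 5, cfl = 0.3,
                               boundary = boundary_spec()) {
  dt <- compute_dt(cfl, medium$grid$dx, max(medium$c0), f0)
  spp <- round(1 / (f0 * dt))
  nt <- as.integer(round(n_cycles * spp))
  n_demod <- as.integer(integrate_cycles * spp)
  if (n_demod >= nt) abort("integration window longer than the simulation")
  res <- sim_core(medium, sources, dt, nt, boundary,
                  demod = list(f0 = f0, n_steps = n_demod))
  list(amplitude = res$amplitude, phase = wrap_phase(res$phase), dt = dt)
}

#' Extract steady-state phase and amplitude from sensor traces
#'
#' Quadrature demodulation at `f0`: after discarding the initial `discard`
#' fraction of the trace (switch-on transients), the last whole number of
#' drive periods is correlated against sin/cos at `f0`. Over an integer
#' number of periods the quadrature pair is exactly orthogonal to any
#' harmonic of `f0`, so residual harmonics do not bias the phase. Phase is
#' reported in (-pi, pi] with the convention `p ~ A sin(2 pi f0 t + phase)`,
#' `t` measured from the simulation start.
#'
#' @param record a `sensor_record` from [run_simulation()].
#' @param f0 drive frequency, Hz. Must be an exact subharmonic of the
#'   sampling rate (guaranteed when `dt` came from [compute_dt()] with this
#'   `f0`).
#' @param discard fraction of the trace to drop from the front, default 0.6.
#' @param min_periods smallest acceptable number of retained whole periods.
#' @return list with numeric vectors `phase` (radians) and `amplitude` (Pa),
#'   one entry per sensor.
#' @export
steady_state_phase <- function(record, f0, discard = 0.6, min_periods = 5L) {
  stopifnot(inherits(record, "sensor_record"))
  check_positive_scalar(f0, "f0")
  if (discard < 0 || discard >= 1) abort("`discard` must lie in [0, 1)")
  dt <- record$dt
  spp_exact <- 1 / (f0 * dt)
  spp <- round(spp_exact)
  if (spp < 4L || abs(spp_exact - spp) > 1e-6 * spp) {
    abort("f0 = %.4g Hz is not resolvable with dt = %.4g s", f0, dt)
  }
  nt <- nrow(record$pressures)
  keep <- nt - floor(nt * discard)
  n_per <- floor(keep / spp)
  if (n_per < min_periods) {
    abort("retained trace spans %d whole periods; need at least %d",
          n_per, min_periods)
  }
  win <- (nt - n_per * spp + 1L):nt
  t_win <- record$t0 + (win - 1L) * dt
  s <- sin(2 * pi * f0 * t_win)
  c_ <- cos(2 * pi * f0 * t_win)
  P <- record$pressures[win, , drop = FALSE]
  Is <- colSums(P * s)
  Ic <- colSums(P * c_)
  half_n <- length(win) / 2
  list(phase = wrap_phase(atan2(Ic, Is)),
       amplitude = sqrt(Is^2 + Ic^2) / half_n)
}
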