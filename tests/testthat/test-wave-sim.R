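test_that("time step follows CFL and divides the drive period exactly", {
  expect_equal(compute_dt(0.3, 1e-4, 3000), 1e-8)
  dt <- compute_dt(0.3, 1e-4, 3000, f0 = 2e6)
  expect_equal(dt, 1e-8)
  expect_equal((1 / 2e6) / dt, round((1 / 2e6) / dt))
  dt2 <- compute_dt(0.3, 2e-4, 2800, f0 = 1e6)
  expect_equal((1 / 1e6) / dt2, round((1 / 1e6) / dt2))
  expect_lte(dt2, 0.3 * 2e-4 / 2800)
  expect_error(compute_dt(1.5, 1e-4, 3000), "cfl")
  expect_error(compute_dt(0, 1e-4, 3000), "cfl")
})

test_that("zero-amplitude source produces an identically zero record", {
  g <- make_grid(c(48, 28) * 2e-4, 2e-4, 1e6, 1482)
  med <- homogeneous_medium(g, water0())
  rec <- run_simulation(med, source_spec(c(10L, 10L), f0 = 1e6,
                                         amplitude = 0),
                        cbind(30L, 10L), 10 / 1e6)
  expect_true(all(rec$pressures == 0))
})

test_that("sensors must lie inside the grid", {
  g <- make_grid(c(48, 28) * 2e-4, 2e-4, 1e6, 1482)
  med <- homogeneous_medium(g, water0())
  expect_error(run_simulation(med, source_spec(c(10L, 10L), f0 = 1e6),
                              cbind(60L, 10L), 5e-6), "outside the grid")
})

test_that("free-field phase matches the exact cylindrical wave", {
  expect_lt(study_free_field_phase(), 2)
})

test_that("plane-wave amplitude decays by the analytic power law", {
  expect_lt(study_attenuation(), 0.03)
})

test_that("a lossless burst conserves acoustic energy in a periodic domain", {
  f0 <- 1e6
  dx <- 1482 / f0 / 8
  g <- make_grid(c(64, 64) * dx, dx, f0, 1482)
  med <- homogeneous_medium(g, water0())
  dt <- compute_dt(0.3, dx, 1482, f0)
  spp <- round(1 / (f0 * dt))
  t_burst <- seq_len(3L * spp) * dt
  wf <- sin(2 * pi * f0 * t_burst) * sin(pi * t_burst / max(t_burst))^2
  nt_total <- 23L * spp
  rec <- run_simulation(med, source_spec(c(32L, 32L), waveform = wf),
                        cbind(32L, 32L), nt_total * dt,
                        boundary = boundary_spec("periodic"),
                        f0 = f0, track_energy = TRUE)
  e <- rec$energy
  window <- (3L * spp + 1L):nt_total   # after the source switches off
  # the instantaneous sum oscillates within a period because u lives on
  # half-steps; the physical invariant is the period-averaged energy
  per_period <- vapply(split(e[window], (seq_along(window) - 1L) %/% spp),
                       mean, 0)
  expect_lt(diff(range(per_period)) / mean(per_period), 0.01)
})

test_that("solver output is invariant under whole-voxel scene translation", {
  f0 <- 1e6
  dx <- 1482 / f0 / 8
  g <- make_grid(c(80, 40) * dx, dx, f0, 1482)
  run_at <- function(shift) {
    c0 <- array(1482, g$n)
    c0[(30:36) + shift, 12:16] <- 2800   # small bone block
    rho <- array(1000, g$n); rho[(30:36) + shift, 12:16] <- 1900
    med <- medium_map(g, rho, c0, 0, 2)
    rec <- run_simulation(med, source_spec(c(20L + shift, 20L), f0 = f0),
                          cbind(60L + shift, 20L), 18 / f0)
    rec$pressures[, 1]
  }
  a <- run_at(0L)
  b <- run_at(3L)
  # residual asymmetry comes only from the changed distance to the PML
  expect_lt(max(abs(a - b)) / max(abs(a)), 5e-3)
})

test_that("free-field phase error shrinks from lambda/4 to lambda/12 sampling", {
  f0 <- 1e6; c0 <- 1482
  err_at <- function(ppw) {
    dx <- c0 / f0 / ppw
    g <- make_grid(c(16e-3, 9.2e-3), dx, f0, c0)
    med <- homogeneous_medium(g, water0())
    src <- holofocus:::coord_to_index(g, matrix(c(4.2e-3, 4.6e-3), 1))
    sens <- holofocus:::coord_to_index(
      g, cbind(c(7.5e-3, 11.5e-3), 4.6e-3))
    rec <- run_simulation(med, source_spec(src, f0 = f0), sens,
                          22 / f0 + 8e-3 / c0)
    ph <- steady_state_phase(rec, f0)
    xy <- holofocus:::index_to_coord(g, sens)
    r <- xy[, 1] - holofocus:::index_to_coord(g, src)[1]
    k <- 2 * pi * f0 / c0
    abs(wrap_deg((ph$phase[2] - ph$phase[1]) -
                   (cyl_phase(k, r[2]) - cyl_phase(k, r[1]))))
  }
  errs <- vapply(c(4, 8, 12), err_at, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("transfer phase is reciprocal in a heterogeneous lossless medium", {
  f0 <- 1e6
  dx <- 1482 / f0 / 8
  g <- make_grid(c(80, 80) * dx, dx, f0, 1482)
  bone <- material_preset("bone-lossless", 1900, 2800, 0)
  med <- synthetic_skull_shell(g, c(7.4e-3, 7.4e-3), c(4e-3, 3e-3), 0.7e-3,
                               inner = water0(), shell_mat = bone,
                               outer = water0())
  a <- c(40L, 40L)   # inside the cavity
  b <- c(40L, 14L)   # below the shell
  transfer <- function(src, snk) {
    rec <- run_simulation(med, source_spec(src, f0 = f0),
                          matrix(snk, 1), 25 / f0)
    steady_state_phase(rec, f0)$phase
  }
  expect_lt(abs(wrap_deg(transfer(a, b) - transfer(b, a))), 2)
})
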