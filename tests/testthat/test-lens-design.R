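test_that("wavenumber is 2 pi f / c", {
  expect_equal(wavenumber(1482, 1e6), 4239.7, tolerance = 1e-4)
  expect_equal(wavenumber(3.03e6 / 1170, 2e6), 4851.6, tolerance = 1e-3)
  expect_equal(wavenumber(1482, 2e6), 2 * wavenumber(1482, 1e6))
})

test_that("thickness design inverts the phase relation within its 2 pi span", {
  grid <- sim_grid(c(3L, 1L), 1e-4)
  mk <- function(ph) holofocus:::new_phase_map(ph, rep(1, length(ph)), 1e-4,
                                               recording_plane(2, 1), 1L,
                                               list(seq_along(ph)), grid, 1e6)
  # forced arithmetic: dk = 2000 rad/m, dphi = 2 -> T0 - T = 1 mm
  f0 <- 1e6
  c_B <- 1000
  c_A <- 1 / (1 / c_B - 2000 / (2 * pi * f0))   # makes k_B - k_A = 2000
  mats <- lens_materials(c_A, c_B, T0 = 5e-3, T_min = 0.2e-3)
  tm <- phase_to_thickness(mk(c(0, 2, -1)), mats, f0)
  expect_equal(tm$T[1], 5e-3)                      # dphi = 0 -> T0
  expect_equal(tm$T0 - tm$T[2], 1e-3, tolerance = 1e-12)
  # bounds invariant
  expect_true(all(tm$T <= tm$T0 + 1e-15))
  expect_true(all(tm$T >= mats$T_min))
  # monotonicity: larger wrapped delay -> smaller thickness for k_B > k_A
  ph <- seq(0.1, 2 * pi - 0.1, length.out = 3)
  tm2 <- phase_to_thickness(mk(ph), mats, f0)
  expect_true(all(diff(tm2$T) < 0))
  # errors
  expect_error(phase_to_thickness(mk(c(0, 1, 2)),
                                  lens_materials(c_A, c_B, T0 = 3e-3,
                                                 T_min = 0.2e-3), f0),
               "2 pi coverage")
  expect_error(lens_materials(1500, 1500), "different speeds")
})

test_that("phase quantization rounds to step multiples with ties downward", {
  grid <- sim_grid(c(5L, 1L), 1e-4)
  step <- 2 * pi / 10
  pm <- holofocus:::new_phase_map(c(0.6, step / 2, -step / 2, 0, 3.1),
                                  rep(1, 5), 1e-4, recording_plane(2, 1),
                                  1L, list(1:5), grid, 1e6)
  q <- quantize_phase(pm, step)
  expect_equal(q$phase[1], step)            # 0.6 -> one step (0.6283)
  expect_equal(q$phase[2], 0)               # exact half-tie to lower level
  expect_equal(q$phase[4], 0)
  expect_true(all(q$phase > -pi & q$phase <= pi))
  q_all <- quantize_phase(pm, 2 * pi)
  expect_true(all(q_all$phase == 0))
})

test_that("lens solids are watertight with exact column volumes", {
  set.seed(11)
  tmap <- structure(list(T = matrix(runif(30, 0.3e-3, 1.4e-3), 6, 5),
                         pitch = 1e-4, f0 = 2e6),
                    class = "thickness_map")
  base <- 0.5e-3
  mesh <- thickness_mesh(tmap, base = base)
  expect_true(mesh_is_watertight(mesh))
  vol_expected <- sum(tmap$T + base) * (tmap$pitch * 1e3)^2 * 1e3  # mm^3
  expect_equal(mesh_volume(mesh), vol_expected, tolerance = 1e-3)

  # uniform slab and a single raised pixel
  slab <- tmap; slab$T <- matrix(1e-3, 3, 3)
  m_slab <- thickness_mesh(slab, base = base)
  expect_equal(mesh_volume(m_slab), 9 * 0.01 * 1.5, tolerance = 1e-3)
  up <- slab; up$T[2, 2] <- 1.25e-3
  expect_equal(mesh_volume(thickness_mesh(up, base = base)) -
                 mesh_volume(m_slab), 0.01 * 0.25, tolerance = 1e-6)
})

test_that("exported STL resamples to the designed thickness within 1 um", {
  set.seed(12)
  tmap <- structure(list(T = matrix(runif(20, 0.3e-3, 1.4e-3), 5, 4),
                         pitch = 1e-4, f0 = 2e6),
                    class = "thickness_map")
  path <- withr::local_tempfile(fileext = ".stl")
  export_stl(tmap, path, base = 0.5e-3)
  back <- read_stl(path)
  expect_true(mesh_is_watertight(back))
  T_back <- resample_heightfield(back, tmap$pitch, dim(tmap$T), base = 0.5e-3)
  expect_lt(max(abs(T_back - tmap$T)), 1e-6)
})

test_that("exported lens geometry reproduces the designed transmission phase", {
  # design a small 1D map, export to STL, resample the print geometry, and
  # verify by 1D simulation that the realized thicknesses impose the
  # designed phase offsets (impedance-matched media isolate the delay)
  f0 <- 1e6
  c_B <- 1482; rho_B <- 1000
  c_A <- 2590; rho_A <- rho_B * c_B / c_A
  grid <- sim_grid(c(4L, 1L), 4e-4)
  ph_target <- c(0, 1.2, -2.0, 2.9)
  pm <- holofocus:::new_phase_map(ph_target, rep(1, 4), 4e-4,
                                  recording_plane(2, 1), 1L, list(1:4),
                                  grid, f0)
  mats <- lens_materials(c_A, c_B)
  tmap <- phase_to_thickness(pm, mats, f0)
  path <- withr::local_tempfile(fileext = ".stl")
  export_stl(tmap, path, base = 0.5e-3)
  T_real <- as.numeric(resample_heightfield(read_stl(path), tmap$pitch,
                                            c(4L, 1L), base = 0.5e-3))
  dx <- c_B / f0 / 12
  g1 <- make_grid(460 * dx, dx, f0, c_B)
  phase_thru <- function(T_m) {
    c0 <- rep(c_B, g1$n[1]); rho <- rep(rho_B, g1$n[1])
    nv <- round(T_m / dx)
    if (nv > 0) { c0[180:(180 + nv - 1)] <- c_A
                  rho[180:(180 + nv - 1)] <- rho_A }
    med <- medium_map(g1, rho, c0, 0, 2)
    rec <- run_simulation(med, source_spec(matrix(20L, 1, 1), f0 = f0),
                          matrix(380L, 1, 1), 30 / f0 + 380 * dx / c_B)
    steady_state_phase(rec, f0)$phase
  }
  ref <- phase_thru(0)
  sim_offset <- vapply(T_real, function(Tm) phase_thru(Tm) - ref, 0)
  dk <- wavenumber(c_B, f0) - wavenumber(c_A, f0)
  # the simulation grid quantizes each slab to whole voxels; compare the
  # transmitted phase against the lens relation evaluated at the realized
  # (voxel-quantized) thicknesses
  T_sl <- round(T_real / dx) * dx
  for (i in 2:4) {
    designed <- -dk * (T_sl[i] - T_sl[1])
    measured <- -(sim_offset[i] - sim_offset[1])
    expect_lt(abs(wrap_deg(measured - designed)), 5)
  }
  # and the realized thicknesses match the designed map to the voxel size
  expect_lt(max(abs(T_sl - tmap$T)), dx)
})
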