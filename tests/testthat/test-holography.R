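test_that("phase conjugation negates, wraps, and is an involution", {
  grid <- sim_grid(c(4L, 1L), 1e-4)
  pm <- holofocus:::new_phase_map(c(0.3, pi, -0.2, 2.0), rep(1, 4), 1e-4,
                                  recording_plane(2, 1), 1L, list(1:4),
                                  grid, 1e6)
  cj <- conjugate_phase(pm)
  expect_equal(cj$phase, c(-0.3, pi, 0.2, -2.0))  # -pi wraps to +pi
  expect_equal(conjugate_phase(cj)$phase, pm$phase)
  expect_equal(cj$amplitude, pm$amplitude)
})

test_that("steering translates the map by whole pixels with edge fill", {
  grid <- sim_grid(c(6L, 1L), 1e-4)
  pm <- holofocus:::new_phase_map(c(1, 2, 3, 4, 5, 6) / 10, rep(1, 6), 1e-4,
                                  recording_plane(2, 1), 1L, list(1:6),
                                  grid, 1e6)
  expect_equal(steer_map(pm, 0)$phase, pm$phase)
  s2 <- steer_map(pm, 2e-4)
  expect_equal(s2$phase, c(0.1, 0.1, 0.1, 0.2, 0.3, 0.4))
  back <- steer_map(s2, -2e-4)
  expect_equal(back$phase[1:4], pm$phase[1:4])   # overlap region
  expect_error(steer_map(pm, 1.5e-4), "integer multiple")
})

test_that("recording requires >= 20 cycles and a plane clear of targets", {
  med <- homogeneous_medium(sim_grid(c(60L, 60L), 2e-4), water0())
  tg <- target_set(c(6e-3, 8e-3), 1e6)
  expect_error(record_time_reversal(med, tg, recording_plane(2, 13),
                                    n_cycles = 10), "minimum of 20")
  expect_error(record_time_reversal(med, tg, recording_plane(2, 41)),
               "intersects a target")
})

test_that("fresnel map is zero on axis and pi at a half-wave path difference", {
  grid <- study_grid()
  tgt <- c(15e-3, 20e-3)
  fm <- fresnel_phase(study_plane(), tgt, study_f0, 1482, grid)
  xy <- holofocus:::phase_map_coords(fm)
  on_axis <- which.min(abs(xy[, 1] - tgt[1]))
  expect_equal(fm$phase[on_axis], 0, tolerance = 1e-9)
  z <- tgt[2] - xy[on_axis, 2]
  k <- 2 * pi * study_f0 / 1482
  # lateral offset whose path difference is half a wavelength
  lat <- sqrt((z + study_lambda / 2)^2 - z^2)
  ph_half <- wrap_phase(k * (sqrt(z^2 + lat^2) - z))
  expect_equal(abs(ph_half), pi, tolerance = 1e-6)
})

test_that("recorded wavefront matches the analytic cylindrical phase", {
  fw <- study_free_water()
  pm <- fw$record
  xy <- holofocus:::phase_map_coords(pm)
  r <- sqrt(rowSums(sweep(xy, 2, fw$target, `-`)^2))
  k <- 2 * pi * study_f0 / 1482
  mid <- which.min(abs(xy[, 1] - fw$target[1]))
  err <- wrap_deg((pm$phase - pm$phase[mid]) -
                    (cyl_phase(k, r) - cyl_phase(k, r[mid])))
  expect_lt(max(abs(err)), 5)
})

test_that("conjugated free-water recording agrees with the Fresnel map", {
  fw <- study_free_water()
  fm <- fresnel_phase(fw$plane, fw$target, study_f0, 1482,
                      fw$medium$grid)
  d <- fw$conj$phase - fm$phase
  mid <- which.min(abs(holofocus:::phase_map_coords(fm)[, 1] - fw$target[1]))
  err <- wrap_deg(d - d[mid])
  expect_lt(sqrt(mean(err^2)), 10)
})

test_that("free-water refocus peaks within half a wavelength of the target", {
  fw <- study_free_water()
  fd <- focal_deviation(fw$field, fw$target, search_region = fw$region)
  expect_true(all(fd$deviation <= study_lambda / 2))
})

test_that("simultaneous recording equals the coherent sum of single-target maps", {
  f0 <- 1e6
  dx <- 1482 / f0 / 8
  g <- make_grid(c(110, 70) * dx, dx, f0, 1482)
  med <- homogeneous_medium(g, water0())
  # span and targets voxel-symmetric about pixel 56
  plane <- recording_plane(2, 13, span = list(21:91))
  t1 <- drop(holofocus:::index_to_coord(g, matrix(c(46L, 49L), 1)))
  t2 <- drop(holofocus:::index_to_coord(g, matrix(c(66L, 49L), 1)))
  m1 <- record_time_reversal(med, target_set(t1, f0), plane)
  m2 <- record_time_reversal(med, target_set(t2, f0), plane)
  m12 <- record_time_reversal(med, target_set(rbind(t1, t2), f0), plane)
  z <- m1$amplitude * exp(1i * m1$phase) + m2$amplitude * exp(1i * m2$phase)
  err <- wrap_deg(m12$phase - Arg(z))
  expect_lt(sqrt(mean(err^2)), 3)

  # mirror symmetry of the two-target map about the midplane
  ph <- m12$phase
  expect_lt(sqrt(mean(wrap_deg(ph - rev(ph))^2)), 3)
})

test_that("two aberrated targets produce exactly two foci within FWHM", {
  mf <- study_multifocus()
  region <- study_region()
  fd_ref <- focal_deviation(mf$field, mf$targets[1, ], search_region = region)
  det <- count_foci(crop_field(mf$field, region$lo, region$hi),
                    threshold_db = -6,
                    min_separation = max(fd_ref$fwhm, na.rm = TRUE))
  expect_identical(det$count, 2L)
})

test_that("steering the map moves the focus by the commanded offset", {
  fw <- study_free_water()
  steered <- steer_map(fw$conj, 1e-3)   # 5 pixels
  fld <- verify_refocus(fw$medium, steered)
  region <- fw$region
  pos0 <- focal_position(crop_field(fw$field, region$lo, region$hi))
  pos1 <- focal_position(crop_field(fld, region$lo, region$hi))
  fd <- focal_deviation(fw$field, fw$target, search_region = region)
  moved <- pos1[1] - pos0[1]
  expect_lt(abs(abs(moved) - 1e-3), fd$fwhm[1] / 2)
})

test_that("2 pi / 10 phase quantization degrades the focal peak by < 20%", {
  fw <- study_free_water()
  q <- quantize_phase(fw$conj, 2 * pi / 10)
  fld_q <- verify_refocus(fw$medium, q)
  p2_full <- p2_near(fw$field, fw$target)
  p2_q <- p2_near(fld_q, fw$target)
  expect_gt(p2_q / p2_full, 0.8)
})
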