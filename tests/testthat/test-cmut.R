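paper_geom <- function() cmut_geometry(18e-6, 1e-6, 200e-9,
                                       t_i = 120e-9, eps_r = 3.9)

test_that("clamped-plate resonance follows the closed form and its scalings", {
  f <- plate_resonance_air(paper_geom())
  expect_equal(f, 1.2064e7, tolerance = 1e-4)   # frozen closed-form value
  g2 <- cmut_geometry(18e-6, 2e-6, 200e-9)
  expect_equal(plate_resonance_air(g2), 2 * f, tolerance = 1e-10)
  g3 <- cmut_geometry(36e-6, 1e-6, 200e-9)
  expect_equal(plate_resonance_air(g3), f / 4, tolerance = 1e-10)
})

test_that("pull-in voltage scales as g_eff^1.5 and sqrt(k_eff)", {
  g1 <- cmut_geometry(18e-6, 1e-6, 200e-9, t_i = 120e-9)
  g4 <- cmut_geometry(18e-6, 1e-6, 800e-9, t_i = 480e-9)  # g_eff x4
  expect_equal(pull_in_voltage(g4) / pull_in_voltage(g1), 8,
               tolerance = 1e-9)
  stiff <- plate_material(E = 300e9)                      # k_eff x2
  expect_equal(pull_in_voltage(g1, stiff) / pull_in_voltage(g1), sqrt(2),
               tolerance = 1e-9)
  # paper-scale geometry collapses at tens of volts
  v_pi <- pull_in_voltage(paper_geom())
  expect_gt(v_pi, 20); expect_lt(v_pi, 100)
})

test_that("bias softening starts at the plate resonance and falls to zero", {
  geom <- paper_geom()
  expect_equal(softened_resonance(geom, V_dc = 0),
               plate_resonance_air(geom))
  v_pi <- pull_in_voltage(geom)
  fs <- vapply(seq(0, 0.99, length.out = 25) * v_pi,
               function(v) softened_resonance(geom, V_dc = v), 0)
  expect_true(all(diff(fs) < 0))
  expect_lt(fs[25] / fs[1], 0.5)   # approaching zero near pull-in
  expect_error(softened_resonance(geom, V_dc = 1.01 * v_pi), "pull-in")
})

test_that("circuit impedance has the capacitive limit and resonance ordering", {
  p <- circuit_params(131e-12, 137, 0.36e-3, 1.45e-12, 8.53, 0)
  f_lo <- 1e5
  expect_equal(Mod(circuit_impedance(p, f_lo)),
               1 / (2 * pi * f_lo * (p$C0 + p$Cm)), tolerance = 0.02)
  f_s <- series_resonance(p)
  expect_equal(f_s, 6.97e6, tolerance = 1e-3)
  f_a <- f_s * sqrt(1 + p$Cm / p$C0)
  expect_gt(f_a, f_s)
  # |Z| peaks near the antiresonance
  f_grid <- seq(6.5e6, 7.5e6, length.out = 2001)
  expect_equal(f_grid[which.max(Mod(circuit_impedance(p, f_grid)))], f_a,
               tolerance = 5e-3)
  # Hermitian symmetry against an independent evaluation at -f
  manual_neg <- function(pp, f) {
    w <- -2 * pi * f
    zm <- pp$Rm + 1i * w * pp$Lm + 1 / (1i * w * pp$Cm)
    zc <- 1 / (1i * w * pp$C0)
    pp$Rs + zc * zm / (zc + zm)
  }
  f_test <- c(2e6, 6.9e6, 9e6)
  expect_equal(Conj(circuit_impedance(p, f_test)), manual_neg(p, f_test))
})

test_that("circuit fitting recovers parameters and flags non-resonant spectra", {
  truth <- circuit_params(131e-12, 137, 0.36e-3, 1.45e-12, 8.53, 0)
  f <- seq(3e6, 12e6, length.out = 300)
  fit <- fit_circuit(synthetic_impedance(truth, f))
  for (nm in c("C0", "Rm", "Lm", "Cm", "Rs")) {
    expect_lt(abs(fit$params[[nm]] / truth[[nm]] - 1), 1e-3)
  }
  cap_only <- impedance_spectrum(f, 1 / (1i * 2 * pi * f * 1e-10))
  expect_error(fit_circuit(cap_only), "no resonance in band")
})

test_that("impedance spectra roundtrip through CSV", {
  truth <- circuit_params(131e-12, 137, 0.36e-3, 1.45e-12, 8.53, 0)
  sp <- synthetic_impedance(truth, seq(4e6, 9e6, length.out = 50), bias = 47)
  path <- withr::local_tempfile(fileext = ".csv")
  write_impedance_csv(sp, path)
  back <- read_impedance_csv(path)
  expect_equal(back$frequencies, sp$frequencies)
  expect_equal(back$Z, sp$Z)
  expect_equal(back$bias, 47)
})

test_that("impulse spectrum recovers a Gaussian burst's center and bandwidth", {
  dt <- 1e-8
  t <- seq(0, 80e-6, by = dt)
  sig_t <- 1.5e-6
  trace <- exp(-(t - 40e-6)^2 / (2 * sig_t^2)) * sin(2 * pi * 2e6 * t)
  sp <- impulse_spectrum(trace, dt)
  sig_f <- 1 / (2 * pi * sig_t)
  expect_equal(sp$center, 2e6, tolerance = 0.01)
  expect_equal(sp$bandwidth, 2 * sig_f * sqrt(2 * log(2)), tolerance = 0.03)
  # time-shift invariance of the magnitude spectrum
  trace2 <- exp(-(t - 25e-6)^2 / (2 * sig_t^2)) * sin(2 * pi * 2e6 * t)
  sp2 <- impulse_spectrum(trace2, dt)
  expect_equal(sp2$center, sp$center, tolerance = 1e-3)
  expect_equal(sp2$bandwidth, sp$bandwidth, tolerance = 1e-2)
  # a long pure tone collapses to the spectral-resolution floor
  tone <- sin(2 * pi * 2e6 * t)
  sp3 <- impulse_spectrum(tone, dt, window = "none")
  expect_lt(sp3$bandwidth, 3 / (length(t) * dt))
  expect_error(impulse_spectrum(trace[1:32], dt), "64 samples")
})

test_that("areal mass converts thickness and density to g/cm^2", {
  expect_equal(areal_mass(725e-6, 2330), 0.169, tolerance = 1e-3)
  expect_identical(areal_mass(0, 2330), 0)
  expect_equal(areal_mass(725e-6, 4660), 2 * areal_mass(725e-6, 2330))
})
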