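# Shared desk-scale study computations, memoised so the acceptance tests
# and module tests reuse one simulation each. All runs are 2D at 1 MHz on
# a 0.2 mm grid (lambda/7.4 in water); the methods vignette documents the
# configuration.

.study <- new.env(parent = emptyenv())

study_get <- function(name, compute) {
  if (!exists(name, .study)) assign(name, compute(), .study)
  get(name, .study)
}

study_f0 <- 1e6
study_lambda <- 1482 / study_f0

study_grid <- function() make_grid(c(30e-3, 36e-3), 0.2e-3, study_f0, 1482)

study_plane <- function() recording_plane(2, 13, span = list(26:126))

study_region <- function(tall = FALSE) {
  list(lo = c(6e-3, 14e-3), hi = c(24e-3, if (tall) 28e-3 else 26e-3))
}

# smooth half-cap skull shell (the standard aberrator)
study_shell <- function() {
  synthetic_skull_shell(study_grid(), c(15e-3, 17e-3), c(12e-3, 8e-3),
                        0.8e-3, cap = list(axis = 2, sign = -1))
}

# roughened cap: sinusoidal thickness modulation emulating suture-scale
# variability (the deliberately aberrating configuration)
study_shell_rough <- function() {
  synthetic_skull_shell(study_grid(), c(15e-3, 17e-3), c(12e-3, 8e-3),
                        0.8e-3, cap = list(axis = 2, sign = -1),
                        thickness_mod = list(amplitude = 0.5e-3,
                                             period = 4e-3, axis = 1))
}

# free-water record + conjugate + refocus. The full-width aperture and a
# shallower target give a high Fresnel number, so the diffraction focal
# shift of a one-sided finite aperture stays well below lambda/2 and the
# refocusing accuracy itself is what the oracle measures.
study_free_water <- function() {
  study_get("free_water", function() {
    grid <- study_grid()
    med <- homogeneous_medium(grid, water0())
    tgt <- c(15e-3, 15e-3)
    plane <- recording_plane(2, 13)
    pm <- record_time_reversal(med, target_set(tgt, study_f0), plane)
    conj <- conjugate_phase(pm)
    fld <- verify_refocus(med, conj)
    list(medium = med, target = tgt, plane = plane, record = pm,
         conj = conj, field = fld,
         region = list(lo = c(6e-3, 10e-3), hi = c(24e-3, 24e-3)))
  })
}

# dual-target recording + refocus through the smooth cap shell
study_multifocus <- function() {
  study_get("multifocus", function() {
    med <- study_shell()
    tg <- rbind(c(10.5e-3, 20e-3), c(19.5e-3, 20e-3))
    pm <- record_time_reversal(med, target_set(tg, study_f0), study_plane())
    fld <- verify_refocus(med, conjugate_phase(pm))
    list(medium = med, targets = tg, record = pm, field = fld)
  })
}

# corrected vs Fresnel fields through the roughened shell, single target
study_fresnel_contrast <- function() {
  study_get("fresnel_contrast", function() {
    med <- study_shell_rough()
    tgt <- c(15e-3, 20e-3)
    pm <- record_time_reversal(med, target_set(tgt, study_f0), study_plane())
    corrected <- verify_refocus(med, conjugate_phase(pm))
    fresnel <- verify_refocus(med, fresnel_phase(study_plane(), tgt,
                                                 study_f0, 1482,
                                                 med$grid))
    list(medium = med, target = tgt, corrected = corrected,
         fresnel = fresnel)
  })
}

# five seeded targets refocused through the roughened shell
study_seeded_refocus <- function() {
  study_get("seeded_refocus", function() {
    med <- study_shell_rough()
    set.seed(1)
    tx <- runif(5, 9e-3, 21e-3)
    ty <- runif(5, 18e-3, 21e-3)
    region <- study_region(tall = TRUE)
    lapply(seq_len(5), function(i) {
      tgt <- c(tx[i], ty[i])
      pm <- record_time_reversal(med, target_set(tgt, study_f0),
                                 study_plane())
      fld <- verify_refocus(med, conjugate_phase(pm))
      list(target = tgt,
           deviation = focal_deviation(fld, tgt, search_region = region))
    })
  })
}

# free-field phase study at dx = lambda/10 against the exact cylindrical
# oracle; returns worst absolute phase error in degrees
study_free_field_phase <- function() {
  study_get("free_field_phase", function() {
    dx <- study_lambda / 10
    g <- make_grid(c(140, 60) * dx, dx, study_f0, 1482)
    med <- homogeneous_medium(g, water0())
    src_idx <- matrix(c(20L, 30L), 1)
    dists <- c(30L, 50L, 70L, 90L, 110L)
    sens <- cbind(20L + dists, 30L)
    dur <- 25 / study_f0 + max(dists) * dx / 1482
    rec <- run_simulation(med, source_spec(src_idx, f0 = study_f0), sens, dur)
    ph <- steady_state_phase(rec, study_f0)
    r <- dists * dx
    k <- 2 * pi * study_f0 / 1482
    meas <- ph$phase - ph$phase[1]
    orac <- cyl_phase(k, r) - cyl_phase(k, r[1])
    max(abs(wrap_deg(meas - orac)))
  })
}

# 1D power-law attenuation study (gamma = 1.5, soft-tissue-scale alpha0);
# returns worst relative amplitude-ratio error vs the analytic law
study_attenuation <- function() {
  study_get("attenuation", function() {
    alpha0 <- 2; gam <- 1.5
    dx <- study_lambda / 8
    g <- make_grid(400 * dx, dx, study_f0, 1482)
    med <- medium_map(g, 1000, 1482, alpha0, gam)
    src <- source_spec(matrix(30L, 1, 1), f0 = study_f0)
    sens <- matrix(c(100L, 175L, 250L, 325L), ncol = 1)
    dur <- 25 / study_f0 + 325 * dx / 1482
    rec <- run_simulation(med, src, sens, dur)
    ph <- steady_state_phase(rec, study_f0)
    x_cm <- (sens[, 1] - sens[1, 1]) * dx * 100
    pred <- 10^(-alpha0 * (study_f0 / 1e6)^gam * x_cm / 20)
    got <- ph$amplitude / ph$amplitude[1]
    max(abs(got[-1] / pred[-1] - 1))
  })
}
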