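# Lumped electromechanical model of a capacitive micromachined ultrasonic
# transducer (CMUT): clamped-plate resonance, electrostatic spring
# softening and pull-in, the 6-element equivalent-circuit impedance, and
# spectrum fitting.

EPS0 <- 8.8541878128e-12

#' CMUT cell geometry
#'
#' @param a membrane (cell) radius, m.
#' @param h membrane thickness, m.
#' @param g vacuum gap height, m.
#' @param t_i insulator thickness, m.
#' @param eps_r insulator relative permittivity.
#' @param n_cells number of cells wired in parallel.
#' @param aperture aperture diameter, m.
#' @param substrate substrate thickness, m.
#' @return a `cmut_geometry` object.
#' @export
cmut_geometry <- function(a, h, g, t_i = 120e-9, eps_r = 3.9,
                          n_cells = 1L, aperture = 8e-3,
                          substrate = 725e-6) {
  for (nm in c("a", "h", "g", "t_i", "eps_r", "aperture", "substrate")) {
    check_positive_scalar(get(nm), nm)
  }
  if (n_cells * pi * a^2 > pi * (aperture / 2)^2) {
    abort("total cell area exceeds the aperture area")
  }
  structure(list(a = a, h = h, g = g, t_i = t_i, eps_r = eps_r,
                 n_cells = as.integer(n_cells), aperture = aperture,
                 substrate = substrate),
            class = "cmut_geometry")
}

#' Plate material constants
#'
#' Defaults are single-crystal silicon values commonly used in MEMS design
#' (E = 150 GPa, nu = 0.27, rho = 2330 kg/m^3); all overridable.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio in [0, 0.5).
#' @param rho_m density, kg/m^3.
#' @return a `plate_material` object.
#' @export
plate_material <- function(E = 150e9, nu = 0.27, rho_m = 2330) {
  check_positive_scalar(E, "E")
  if (nu < 0 || nu >= 0.5) abort("`nu` must lie in [0, 0.5)")
  check_positive_scalar(rho_m, "rho_m")
  structure(list(E = E, nu = nu, rho_m = rho_m), class = "plate_material")
}

# lumped equivalents shared by resonance / softening / pull-in:
#   flexural rigidity D = E h^3 / (12 (1 - nu^2))
#   fundamental clamped-plate frequency f = (10.21 / (2 pi a^2)) sqrt(D / (rho h))
#   piston stiffness under uniform pressure k_eff = 64 pi D / a^2
#     (center deflection w0 = P a^4 / (64 D), piston force F = P pi a^2)
#   effective mass m_eff = k_eff / omega0^2 (consistent with the plate
#     fundamental by construction; equals 64/10.21^2 ~ 0.614 of the plate mass)
lumped_plate <- function(geom, mat) {
  D <- mat$E * geom$h^3 / (12 * (1 - mat$nu^2))
  omega0 <- (10.21 / geom$a^2) * sqrt(D / (mat$rho_m * geom$h))
  k_eff <- 64 * pi * D / geom$a^2
  list(D = D, omega0 = omega0, f0 = omega0 / (2 * pi),
       k_eff = k_eff, m_eff = k_eff / omega0^2,
       g_eff = geom$g + geom$t_i / geom$eps_r,
       A_e = pi * geom$a^2)
}

#' Unbiased plate resonance in air
#'
#' Fundamental resonance of the clamped circular membrane,
#' `f = (10.21 / (2 pi a^2)) sqrt(D / (rho h))` with
#' `D = E h^3 / (12 (1 - nu^2))`.
#'
#' @param geom a [cmut_geometry()].
#' @param mat a [plate_material()].
#' @return frequency, Hz.
#' @export
#' @examples
#' plate_resonance_air(cmut_geometry(18e-6, 1e-6, 200e-9))  # ~12 MHz
plate_resonance_air <- function(geom, mat = plate_material()) {
  lumped_plate(geom, mat)$f0
}

# static equilibrium deflection of the lumped parallel-plate model:
# k x (g - x)^2 = eps0 A V^2 / 2, stable root x in [0, g/3)
static_deflection <- function(lp, V) {
  if (V == 0) return(0)
  rhs <- EPS0 * lp$A_e * V^2 / 2
  f <- function(x) lp$k_eff * x * (lp$g_eff - x)^2 - rhs
  # at the stable branch f is increasing from 0 and peaks at x = g/3
  if (f(lp$g_eff / 3) < 0) return(NA_real_)   # beyond pull-in
  uniroot(f, c(0, lp$g_eff / 3), tol = lp$g_eff * 1e-14)$root
}

#' Bias-softened resonance
#'
#' Small-signal resonance under DC bias: the electrostatic force gradient
#' at the bias-deflected equilibrium reduces the net stiffness,
#' `f(V) = f(0) sqrt(1 - k_e / k_eff)` with
#' `k_e = eps0 A V^2 / (g_eff - x(V))^3` evaluated at the static deflection
#' `x(V)`. The frequency decreases monotonically with bias and reaches zero
#' exactly at the pull-in voltage of the same lumped model.
#'
#' @param geom,mat geometry and material.
#' @param V_dc DC bias, volts (0 <= V_dc < pull-in).
#' @return frequency, Hz.
#' @export
softened_resonance <- function(geom, mat = plate_material(), V_dc) {
  if (V_dc < 0) abort("V_dc must be >= 0")
  lp <- lumped_plate(geom, mat)
  x <- static_deflection(lp, V_dc)
  if (is.na(x)) {
    abort("V_dc = %.3g V is at or beyond the pull-in voltage %.3g V",
          V_dc, pull_in_voltage(geom, mat))
  }
  k_e <- EPS0 * lp$A_e * V_dc^2 / (lp$g_eff - x)^3
  arg <- 1 - k_e / lp$k_eff
  if (arg <= 0) {
    abort("V_dc = %.3g V is at or beyond the pull-in voltage", V_dc)
  }
  lp$f0 * sqrt(arg)
}

#' Pull-in voltage
#'
#' Electrostatic collapse threshold of the lumped parallel-plate model:
#' `V_pi = sqrt(8 k_eff g_eff^3 / (27 eps0 A_e))`, with the effective gap
#' `g_eff = g + t_i / eps_r` accounting for the insulator.
#'
#' @param geom,mat geometry and material.
#' @return volts.
#' @export
pull_in_voltage <- function(geom, mat = plate_material()) {
  lp <- lumped_plate(geom, mat)
  sqrt(8 * lp$k_eff * lp$g_eff^3 / (27 * EPS0 * lp$A_e))
}

#' Six-element equivalent-circuit parameters
#'
#' The electrical equivalent circuit of a CMUT near resonance: a motional
#' RLC branch (Rm, Lm, Cm) in parallel with the static capacitance C0, in
#' series with parasitics Rs and Cs. `Cs = 0` denotes an absent (shorted)
#' series capacitor.
#'
#' @param C0 static capacitance, F.
#' @param Rm motional resistance, ohm.
#' @param Lm motional inductance, H.
#' @param Cm motional capacitance, F.
#' @param Rs series resistance, ohm.
#' @param Cs series capacitance, F (0 = absent).
#' @return a `circuit_params` object.
#' @export
circuit_params <- function(C0, Rm, Lm, Cm, Rs = 0, Cs = 0) {
  vals <- c(C0 = C0, Rm = Rm, Lm = Lm, Cm = Cm, Rs = Rs, Cs = Cs)
  if (any(vals < 0)) abort("circuit parameters must be >= 0")
  if (Lm * Cm <= 0) abort("Lm * Cm must be > 0 for a resonant branch")
  structure(as.list(vals), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(paste0("circuit_params: C0 = %.4g pF, Rm = %.4g ohm, ",
                     "Lm = %.4g mH, Cm = %.4g pF, Rs = %.4g ohm, ",
                     "Cs = %.4g pF (f_s = %.4g MHz)\n"),
              x$C0 * 1e12, x$Rm, x$Lm * 1e3, x$Cm * 1e12, x$Rs, x$Cs * 1e12,
              series_resonance(x) / 1e6))
  invisible(x)
}

#' Series (mechanical) resonance of the motional branch
#'
#' @param params a [circuit_params()].
#' @return `1 / (2 pi sqrt(Lm Cm))`, Hz.
#' @export
series_resonance <- function(params) {
  1 / (2 * pi * sqrt(params$Lm * params$Cm))
}

#' Equivalent-circuit impedance
#'
#' `Z(f) = Rs + 1/(j w Cs) + [ 1/(j w C0) || (Rm + j w Lm + 1/(j w Cm)) ]`;
#' with `Cs = 0` the series capacitor is treated as absent (short).
#'
#' @param params a [circuit_params()].
#' @param f frequency vector, Hz.
#' @return complex impedance, ohms.
#' @export
circuit_impedance <- function(params, f) {
  if (any(f <= 0)) abort("frequencies must be > 0")
  w <- 2 * pi * f
  z_mot <- params$Rm + 1i * w * params$Lm + 1 / (1i * w * params$Cm)
  z_c0 <- 1 / (1i * w * params$C0)
  z_par <- z_c0 * z_mot / (z_c0 + z_mot)
  z_ser <- params$Rs + if (params$Cs > 0) 1 / (1i * w * params$Cs) else 0
  z_ser + z_par
}

#' Impedance spectrum container
#'
#' @param frequencies strictly increasing frequency vector, Hz.
#' @param Z complex impedance, ohms.
#' @param bias DC bias label, volts.
#' @return an `impedance_spectrum` object.
#' @export
impedance_spectrum <- function(frequencies, Z, bias = NA_real_) {
  if (any(diff(frequencies) <= 0)) {
    abort("frequencies must be strictly increasing")
  }
  if (any(!is.finite(Re(Z))) || any(!is.finite(Im(Z)))) {
    abort("impedance must be finite")
  }
  structure(list(frequencies = frequencies, Z = Z, bias = bias),
            class = "impedance_spectrum")
}

#' Read / write impedance spectra as CSV
#'
#' Columns: `frequency_hz`, `re_ohm`, `im_ohm`, `bias_v`.
#'
#' @param path CSV path.
#' @return an `impedance_spectrum` / the path invisibly.
#' @export
read_impedance_csv <- function(path) {
  d <- read.csv(path)
  need <- c("frequency_hz", "re_ohm", "im_ohm")
  if (!all(need %in% names(d))) {
    abort("impedance CSV must have columns %s", paste(need, collapse = ", "))
  }
  bias <- if ("bias_v" %in% names(d)) d$bias_v[1L] else NA_real_
  impedance_spectrum(d$frequency_hz, complex(real = d$re_ohm,
                                             imaginary = d$im_ohm), bias)
}

#' @rdname read_impedance_csv
#' @param spec an `impedance_spectrum`.
#' @export
write_impedance_csv <- function(spec, path) {
  write.csv(data.frame(frequency_hz = spec$frequencies,
                       re_ohm = Re(spec$Z), im_ohm = Im(spec$Z),
                       bias_v = spec$bias),
            path, row.names = FALSE)
  invisible(path)
}

#' Synthesize an impedance spectrum from circuit parameters
#'
#' Evaluates the circuit model and optionally applies multiplicative
#' complex Gaussian noise of relative scale `noise`.
#'
#' @param params a [circuit_params()].
#' @param frequencies Hz.
#' @param noise relative noise level (0 = exact).
#' @param bias bias label, volts.
#' @return an `impedance_spectrum`.
#' @export
synthetic_impedance <- function(params, frequencies, noise = 0,
                                bias = NA_real_) {
  Z <- circuit_impedance(params, frequencies)
  if (noise > 0) {
    n <- length(Z)
    Z <- Z * (1 + noise * complex(real = rnorm(n), imaginary = rnorm(n)) /
                sqrt(2))
  }
  impedance_spectrum(frequencies, Z, bias)
}

# detect whether a spectrum contains a motional resonance: relative
# deviation of the admittance from the best pure-capacitor fit
has_resonance <- function(spec) {
  w <- 2 * pi * spec$frequencies
  Y <- 1 / spec$Z
  C_fit <- sum(w * Im(Y)) / sum(w^2)          # LS fit Im(Y) = w C
  resid <- Mod(Y - 1i * w * C_fit) / Mod(Y)
  max(resid) > 0.02
}

#' Fit the 6-element equivalent circuit to an impedance spectrum
#'
#' Levenberg-Marquardt least squares on the stacked real and imaginary
#' parts, each point weighted by `1/|Z|` and by its log-frequency spacing.
#' C0, Rm, Lm, Cm and Rs are fitted in log space (positivity); the series
#' capacitor is fitted as an elastance (`1/Cs`, with 0 meaning absent).
#' Initial values are derived from the spectrum (C0 from the low-frequency
#' capacitive branch, the motional branch from the admittance-circle peak);
#' up to `restarts` deterministic perturbed restarts are attempted on
#' non-convergence.
#'
#' @param spectrum an [impedance_spectrum()] spanning the resonance.
#' @param init optional [circuit_params()] starting point.
#' @param restarts maximum number of perturbed restarts.
#' @return list with `params` (a `circuit_params`), `residual` (weighted
#'   RMS relative residual), and `rel_confidence` (per-parameter relative
#'   half-widths from the Jacobian).
#' @export
fit_circuit <- function(spectrum, init = NULL, restarts = 4L) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  Z <- spectrum$Z
  if (!has_resonance(spectrum)) {
    abort("no resonance in band: spectrum is indistinguishable from a capacitor")
  }
  w <- 2 * pi * f
  # automatic initials
  if (is.null(init)) {
    C0_i <- -1 / (w[1L] * Im(Z[1L]))
    if (!is.finite(C0_i) || C0_i <= 0) C0_i <- 1e-10
    Y <- 1 / Z
    Ym <- Y - 1i * w * C0_i
    ipk <- which.max(Re(Ym))
    f_s <- f[ipk]
    Rm_i <- 1 / max(Re(Ym[ipk]), 1e-6)
    # -3 dB width of the Re(Ym) peak -> quality factor
    half <- Re(Ym[ipk]) / 2
    above <- which(Re(Ym) > half)
    bw <- max(f[max(above)] - f[min(above)], diff(range(f)) / 50)
    Q_i <- f_s / bw
    Lm_i <- Rm_i * Q_i / (2 * pi * f_s)
    Cm_i <- 1 / ((2 * pi * f_s)^2 * Lm_i)
    init <- circuit_params(C0_i, Rm_i, Lm_i, Cm_i, Rs = 1, Cs = 0)
  }
  dlf <- diff(log(f))
  wt <- sqrt(c(dlf[1L], (dlf[-1L] + dlf[-length(dlf)]) / 2,
               dlf[length(dlf)]))
  wt <- wt / Mod(Z)
  model <- function(p) {
    # p = log(C0, Rm, Lm, Cm, Rs) [, log(1/Cs)]
    cp <- list(C0 = exp(p[1L]), Rm = exp(p[2L]), Lm = exp(p[3L]),
               Cm = exp(p[4L]), Rs = exp(p[5L]), Cs = 0)
    zm <- circuit_impedance(cp, f)
    if (length(p) == 6L) zm <- zm + exp(p[6L]) / (1i * w)  # series elastance
    c(wt * (Re(zm) - Re(Z)), wt * (Im(zm) - Im(Z)))
  }
  p0 <- c(log(init$C0), log(init$Rm), log(init$Lm), log(init$Cm),
          log(max(init$Rs, 1e-3)))
  dev_scale <- sum((wt * c(Re(Z), Im(Z)))^2)
  run_lm <- function(p_start) {
    best <- NULL
    for (r in 0:restarts) {
      pr <- p_start
      if (r > 0) pr[1:5] <- p_start[1:5] + 0.2 * r * (-1)^((1:5) + r)
      fit <- try(minpack.lm::nls.lm(pr, fn = model,
                                    control = minpack.lm::nls.lm.control(
                                      maxiter = 500)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      # a restart must improve materially, not win a floating-point tie
      if (is.null(best) || fit$deviance < best$deviance * 0.99) best <- fit
      if (!is.null(best) && best$info %in% 1:4 &&
          best$deviance < 1e-6 * dev_scale) break
    }
    best
  }
  # stage 1: series capacitor absent (the usual case, and the elastance is
  # only weakly identifiable); stage 2 frees it only when the residual says
  # the 5-element model is structurally wrong
  best <- run_lm(p0)
  if (is.null(best)) abort("circuit fit did not converge")
  elast <- 0
  if (init$Cs > 0 || best$deviance > 1e-6 * dev_scale) {
    elast_seed <- if (init$Cs > 0) 1 / init$Cs else {
      1e-3 * 2 * pi * f[1L] * median(Mod(Z))
    }
    fit6 <- run_lm(c(best$par[1:5], log(elast_seed)))
    if (!is.null(fit6) && fit6$deviance < best$deviance * 0.5) {
      best <- fit6
      elast <- exp(best$par[6L])
    }
  }
  p <- best$par
  # report Cs = 0 (absent) when its reactance is negligible against |Z|
  elast_floor <- 1e-6 * min(w) * median(Mod(Z))
  params <- circuit_params(exp(p[1L]), exp(p[2L]), exp(p[3L]), exp(p[4L]),
                           exp(p[5L]),
                           if (elast > elast_floor) 1 / elast else 0)
  # relative confidence from the Jacobian (log-space params: already relative)
  rel <- rep(NA_real_, 6L)
  cv <- try(solve(best$hessian), silent = TRUE)
  if (!inherits(cv, "try-error")) {
    s2 <- best$deviance / max(1, 2 * length(f) - length(p))
    rel[seq_along(p)] <- sqrt(pmax(diag(cv), 0) * s2)
  }
  list(params = params,
       residual = sqrt(best$deviance / sum((wt * c(Re(Z), Im(Z)))^2)),
       rel_confidence = setNames(rel, c("C0", "Rm", "Lm", "Cm", "Rs", "Cs")),
       converged = best$info %in% 1:4)
}

#' Center frequency and bandwidth of an impulse response
#'
#' Magnitude spectrum of the (optionally windowed) pressure trace via FFT;
#' the band is delimited where the magnitude falls `level_db` below the
#' peak (linear interpolation between bins), the center frequency is the
#' band midpoint and the bandwidth its width. The -6 dB convention is the
#' default; use `level_db = -3` for the half-power convention.
#'
#' @param trace pressure samples, Pa (length >= 64).
#' @param dt sample interval, s.
#' @param window "hann" or "none".
#' @param level_db band edge level relative to the peak, dB (negative).
#' @return list with `center`, `bandwidth` (Hz), and the `spectrum`
#'   (data.frame of frequency and magnitude).
#' @export
impulse_spectrum <- function(trace, dt, window = c("hann", "none"),
                             level_db = -6) {
  window <- match.arg(window)
  if (length(trace) < 64L) abort("trace must have at least 64 samples")
  if (any(!is.finite(trace))) abort("trace must be finite")
  check_positive_scalar(dt, "dt")
  n <- length(trace)
  wfun <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  } else rep(1, n)
  S <- fft(trace * wfun)
  nh <- floor(n / 2)
  freq <- (0:(nh - 1L)) / (n * dt)
  mag <- Mod(S[1:nh])
  ipk <- which.max(mag)
  thr <- mag[ipk] * 10^(level_db / 20)
  edge <- function(dir) {
    ii <- if (dir < 0) seq(ipk, 1L) else seq(ipk, nh)
    below <- which(mag[ii] < thr)
    if (!length(below)) {
      abort("band edge outside the sampled frequency range")
    }
    j <- ii[below[1L]]
    i <- j + ifelse(dir < 0, 1L, -1L)
    freq[i] + (freq[j] - freq[i]) * (mag[i] - thr) / (mag[i] - mag[j])
  }
  lo <- edge(-1); hi <- edge(+1)
  list(center = (lo + hi) / 2, bandwidth = hi - lo,
       spectrum = data.frame(frequency = freq, magnitude = mag))
}

#' Areal mass of the transducer die
#'
#' `thickness * density`, reported in grams per square centimeter -- the
#' figure of merit for head-mounted devices (a 725 um silicon substrate
#' weighs ~0.17 g per cm^2 of aperture).
#'
#' @param thickness substrate thickness, m.
#' @param density substrate density, kg/m^3.
#' @return g/cm^2.
#' @export
#' @examples
#' areal_mass(725e-6, 2330)  # ~0.169
areal_mass <- function(thickness, density) {
  if (thickness < 0) abort("thickness must be >= 0")
  check_positive_scalar(density, "density")
  thickness * density * 0.1   # kg/m^2 -> g/cm^2
}
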