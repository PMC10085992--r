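# Independent oracles used across the suite.

# exact phase of the outgoing 2D cylindrical wave under the package's
# sin(w t + phase) convention: phase = -arg H0^(1)(k r) + const
cyl_phase <- function(k, r) -atan2(besselY(k * r, 0), besselJ(k * r, 0))

# wrapped difference in degrees
wrap_deg <- function(x) atan2(sin(x), cos(x)) * 180 / pi

# brute-force (triple-loop) ellipsoidal shell voxel classifier, independent
# of the vectorized implementation
brute_shell_count <- function(grid, center, semi, thickness) {
  n <- grid$n
  cnt <- 0L
  inner <- pmax(semi - thickness, 0)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    x <- grid$origin + (c(i, j, k) - 1) * grid$dx
    u <- (x - center)
    r_out <- sum((u / semi)^2)
    r_in <- sum((u / inner)^2)
    if (r_out <= 1 && r_in >= 1) cnt <- cnt + 1L
  }
  cnt
}

# lossless water with no absorption (fast solver path for propagation tests)
water0 <- function() material_preset("water-lossless", 1000, 1482, 0)

# peak |p|^2 in a small box around a point
p2_near <- function(field, point, radius = 1.5e-3) {
  sub <- crop_field(field, point - radius, point + radius)
  max(sub$amplitude^2)
}
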