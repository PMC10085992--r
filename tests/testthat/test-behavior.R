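test_that("speed and distance follow the step-sum definitions", {
  tr <- trajectory(times = c(0, 2), x = c(0, 6), y = c(0, 8))
  expect_equal(cumulative_distance(tr), 10)
  expect_equal(average_speed(tr), 5)

  # circle traversed once: path length approaches the circumference
  th <- seq(0, 2 * pi, length.out = 721)
  circ <- trajectory(times = seq_along(th) / 30, x = 10 * cos(th),
                     y = 10 * sin(th))
  expect_equal(cumulative_distance(circ), 2 * pi * 10, tolerance = 1e-4)

  # back-and-forth counts path, not displacement
  zig <- trajectory(times = 0:6, x = c(0, 3, 0, 3, 0, 3, 0), y = rep(0, 7))
  expect_equal(cumulative_distance(zig), 18)

  # concatenation additivity
  a <- trajectory(0:3, c(0, 1, 2, 3), c(0, 0, 1, 1))
  b <- trajectory(4:6, c(5, 6, 7), c(1, 2, 2))
  ab <- trajectory(0:6, c(a$x, b$x), c(a$y, b$y))
  joining <- sqrt((b$x[1] - a$x[4])^2 + (b$y[1] - a$y[4])^2)
  expect_equal(cumulative_distance(ab),
               cumulative_distance(a) + cumulative_distance(b) + joining)

  expect_equal(average_speed(ab) * diff(range(ab$times)),
               cumulative_distance(ab))
})

test_that("occupancy weights follow the Gaussian kernel", {
  arena <- arena_grid(c(0, 10), c(0, 10), pitch = 0.5)
  # animal parked exactly on a pixel center
  tr <- trajectory(c(0, 1), x = c(5.25, 5.25), y = c(5.25, 5.25))
  occ <- occupancy_map(tr, arena, sigma = 1)
  i <- which.min(abs(arena$xc - 5.25))
  j <- which.min(abs(arena$yc - 5.25))
  expect_equal(occ$values[i, j], 2)        # weight 1 per frame, 2 frames
  i_sig <- which.min(abs(arena$xc - 6.25)) # one sigma away in x
  expect_equal(occ$values[i_sig, j] / 2, exp(-0.5), tolerance = 1e-12)
})

test_that("occupancy is translation-equivariant and linear in repetition", {
  base <- arena_grid(c(0, 12), c(0, 12), pitch = 0.4)
  moved <- arena_grid(c(3, 15), c(-2, 10), pitch = 0.4)
  tr <- trajectory(0:4 / 30, x = c(5, 5.2, 5.6, 6, 6.1),
                   y = c(6, 6.1, 6.4, 6.2, 6))
  tr_m <- trajectory(tr$times, tr$x + 3, tr$y - 2)
  expect_equal(occupancy_map(tr_m, moved)$values,
               occupancy_map(tr, base)$values)

  rep3 <- trajectory(seq_len(3 * 5) / 90, rep(tr$x, each = 3),
                     rep(tr$y, each = 3))
  expect_equal(total_occupancy(occupancy_map(rep3, base)),
               3 * total_occupancy(occupancy_map(tr, base)))
})

test_that("out-of-arena frames are dropped with a count", {
  arena <- arena_grid(c(0, 10), c(0, 10))
  tr <- trajectory(0:2, x = c(5, 15, 5), y = c(5, 5, 5))
  expect_warning(occ <- occupancy_map(tr, arena), "1 frames outside")
  expect_identical(occ$n_clipped, 1L)
})

test_that("trajectory CSVs load with confidence interpolation", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(frame = 1:5, x = c(10, 20, 999, 40, 50),
                       y = c(5, 10, -999, 20, 25),
                       confidence = c(1, 1, 0.1, 1, 1)),
            path, row.names = FALSE)
  tr <- load_trajectory(path, frame_rate = 30, scale = 0.1,
                        min_confidence = 0.5)
  expect_length(tr$x, 5)
  expect_equal(tr$x[3], 3)   # midpoint of 2 and 4 (scaled)
  expect_equal(tr$y[3], 1.5)

  tr2 <- load_trajectory(path, frame_rate = 30, scale = 0.1)  # no filtering
  expect_equal(tr2$x[3], 99.9)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(frame = c(1, 3, 2), x = 1:3, y = 1:3), bad,
            row.names = FALSE)
  expect_error(load_trajectory(bad, 30), "increasing")
  nocol <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(frame = 1:3, x = 1:3), nocol, row.names = FALSE)
  expect_error(load_trajectory(nocol, 30), "missing columns: y")
})

test_that("synthetic walks are seeded, bounded, and Rayleigh-distributed", {
  arena <- arena_grid(c(0, 30), c(0, 30))
  a <- synthetic_trajectory(200, 30, arena, step_sigma = 0.5, seed = 9)
  b <- synthetic_trajectory(200, 30, arena, step_sigma = 0.5, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= 30 & a$y >= 0 & a$y <= 30))

  still <- synthetic_trajectory(50, 30, arena, step_sigma = 0, seed = 1)
  expect_equal(average_speed(still), 0)

  # uncorrelated Gaussian steps: mean length sigma * sqrt(pi / 2)
  big <- arena_grid(c(0, 500), c(0, 500))
  w <- synthetic_trajectory(10000, 30, big, step_sigma = 0.5,
                            persistence = 0, seed = 2,
                            start = c(250, 250))
  mean_step <- cumulative_distance(w) / (length(w$x) - 1)
  expect_equal(mean_step, 0.5 * sqrt(pi / 2), tolerance = 0.03)
})
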