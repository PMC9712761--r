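test_that("generators are seed-reproducible", {
  expect_identical(gen_dwell_times(0.5, 1, 9, 100, seed = 4),
                   gen_dwell_times(0.5, 1, 9, 100, seed = 4))
  t1 <- gen_height_trace(0.5, 900, rate = 1e5, duration = 0.02, seed = 4)
  t2 <- gen_height_trace(0.5, 900, rate = 1e5, duration = 0.02, seed = 4)
  expect_identical(t1$z, t2$z)
  expect_identical(gen_toy_structure(seed = 4), gen_toy_structure(seed = 4))
})

test_that("dwell mixture has the closed-form mean and collapses when pure", {
  d <- gen_dwell_times(0.55, 0.77, 8.2, 1e5, dt = 0.01, seed = 5)
  mix_mean <- 0.55 * 0.77 + 0.45 * 8.2
  expect_lt(abs(mean(d) / mix_mean - 1), 0.02)
  pure <- gen_dwell_times(1, 5, 50, 2e4, dt = 0.01, seed = 6)
  expect_lt(abs(mean(pure) - 5) / 5, 3 * 1 / sqrt(2e4) * 1.1)
  # discretization floor: all dwells are positive frame multiples
  dd <- gen_dwell_times(0.9, 0.2, 5, 1000, dt = 1, seed = 7)
  expect_true(all(dd >= 1))
  expect_true(all(dd == round(dd)))
})

test_that("height-trace occupancy scales linearly with concentration", {
  t1 <- gen_height_trace(0.59, 400, rate = 2e5, duration = 0.4, seed = 8)
  t2 <- gen_height_trace(0.59, 800, rate = 2e5, duration = 0.4, seed = 9)
  f1 <- mean(t1$truth$occupied); f2 <- mean(t2$truth$occupied)
  expect_lt(abs(f2 / f1 - 2), 0.45)
  t0 <- gen_height_trace(0.59, 0, rate = 1e5, duration = 0.05, seed = 10)
  expect_equal(sum(t0$truth$occupied), 0)
  expect_equal(nrow(detect_events(t0)), 0)
})

test_that("mean event dwell relates to the crossing-time scale", {
  # excursion dwells of a Brownian disc detector: tail decay bounded above
  # by the crossing estimate w^2/4D (see the methods vignette)
  tr <- gen_height_trace(0.59, 830, rate = 1e6, duration = 0.5, seed = 11)
  ev <- detect_events(tr)
  tau_cross <- (detection_width(45.125, 1) * 1e-3)^2 / (4 * 0.59)
  tau_fit <- event_dwell_time(ev)
  expect_gt(tau_fit, tau_cross / 20)
  expect_lt(tau_fit, tau_cross)
})

test_that("scripted movies respect their schedule and boundary flags", {
  sch <- data.frame(x = c(6, 6, 7), y = c(4, 8, 2),
                    start = c(1, 10, 20), frames = c(5, 5, 10))
  mv <- gen_occupancy_movie(sch, dims = c(12, 12), n_frames = 40)
  expect_false(mv$truth$complete[1])   # starts at frame 1
  expect_true(all(mv$truth$complete[2:3]))
  expect_equal(sum(mv$movie[6, 8, ]), 5)
  clash <- data.frame(x = c(6, 6), y = c(4, 4), start = c(5, 8), frames = c(5, 3))
  expect_error(gen_occupancy_movie(clash, dims = c(12, 12), n_frames = 40),
               "conflict")
  outside <- data.frame(x = 6, y = 4, start = 38, frames = 10)
  expect_error(gen_occupancy_movie(outside, dims = c(12, 12), n_frames = 40),
               "outside")
})

test_that("empty schedule leaves only the static block", {
  mv <- gen_occupancy_movie(data.frame(x = integer(), y = integer(),
                                       start = integer(), frames = integer()),
                            dims = c(8, 8), n_frames = 5)
  expect_true(all(mv$movie[1:4, , ] == 1))
  expect_true(all(mv$movie[5:8, , ] == 0))
})

test_that("toy structure honors belt bounds and residue classes", {
  at <- gen_toy_structure(belt = 30, height = 60, girdle = TRUE, seed = 12)
  leu <- at$z[at$resid == "LEU"]
  expect_true(all(abs(leu) <= 15.6))
  trp <- at$z[at$resid == "TRP"]
  expect_true(all(abs(trp) > 14.9 & abs(trp) < 18.1))
  expect_error(gen_toy_structure(belt = 70, height = 60), "belt")
})
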