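test_that("scripted movie events are recovered with exact classes and dwells", {
  sch <- data.frame(x = rep(5, 10), y = 2 * (1:10),
                    start = rep(5, 10), frames = rep(3, 10))
  # block rows 1..4: every (5, y) site touches it with exactly one bond
  mv <- gen_occupancy_movie(sch, dims = c(16, 24), n_frames = 100,
                            block = list(x = c(1, 4), y = c(1, 24)))
  ev <- classify_events(mv$movie, dt = 1)
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$bond_class == "1B"))
  expect_true(all(ev$frames == 3))
  expect_true(all(ev$dwell_s == 3))
})

test_that("two-bond events and boundary/incomplete rules are honored", {
  mv <- array(0L, c(8, 8, 40))
  mv[1:4, , ] <- 1L                 # static block
  mv[5, 3, ] <- 1L                  # static protrusion
  mv[5, 4, 10:15] <- 1L             # corner event: neighbors block + protrusion
  mv[5, 6, 1:5] <- 1L               # touches movie start: incomplete
  mv[5, 7, 35:40] <- 1L             # touches movie end: incomplete
  ev <- classify_events(mv, dt = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$bond_class, "2B")
  expect_equal(ev$dwell_s, 6 * 0.5)
  expect_equal(nrow(classify_events(array(0L, c(4, 4, 10)), dt = 1)), 0)
})

test_that("events with a changing neighbor environment are discarded", {
  mv <- array(0L, c(8, 8, 30))
  mv[1:4, , ] <- 1L
  mv[5, 4, 10:20] <- 1L             # the event
  mv[5, 5, 12:14] <- 1L             # a transient neighbor appears mid-event
  ev <- classify_events(mv, dt = 1)
  # the (5,5) event itself changes class too (its neighbor (5,4) is present)
  expect_false(any(ev$x == 5 & ev$y == 4))
})

test_that("censored MLE recovers mixture parameters and refuses tiny samples", {
  d <- gen_dwell_times(0.55, 0.77, 8.2, n = 1096, dt = 1, seed = 3)
  f <- fit_exponential_mixture(d, dt = 1)
  expect_lt(abs(f$tau2 - 8.2), 3 * f$se[["tau2"]])
  expect_false(f$degenerate)
  expect_true(f$tau1 < f$tau2)
  # survival function is a proper monotone survival curve
  t <- seq(0, 40, by = 0.5)
  s <- mixture_survival(f, t)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) < 0))
  expect_error(fit_exponential_mixture(d[1:20], dt = 1), "too few")
})

test_that("a single-exponential sample collapses the mixture", {
  set.seed(9)
  d <- pmax(1, ceiling(rexp(10000, 1 / 5)))
  f <- fit_exponential_mixture(d, dt = 1)
  expect_true(f$degenerate)
  expect_lt(abs(f$tau_single - 5), 0.2)
  # the fitted mixture mean agrees with the single time constant
  mix_mean <- f$c1 * f$tau1 + (1 - f$c1) * f$tau2
  expect_lt(abs(mix_mean - 5), 0.3)
})

test_that("fixing tau1 reproduces the constrained fitting strategy", {
  d <- gen_dwell_times(0.55, 0.77, 8.2, n = 1096, dt = 1, seed = 13)
  free <- fit_exponential_mixture(d, dt = 1)
  fixed <- fit_exponential_mixture(d, dt = 1, fix_tau1 = 0.7)
  expect_equal(fixed$tau1, 0.7)
  expect_lt(abs(fixed$tau2 - free$tau2), 2 * free$se[["tau2"]])
})

test_that("median tau1 bias at n = 300 stays below 15%", {
  set.seed(42)
  t1s <- replicate(60, {
    d <- gen_dwell_times(0.55, 0.77, 8.2, 300, dt = 1)
    fit_exponential_mixture(d, dt = 1)$tau1
  })
  expect_lt(abs(median(t1s) - 0.77) / 0.77, 0.15)
})

test_that("frame discretization does not bias tau2 (censoring correctness)", {
  set.seed(7)
  disc <- fit_exponential_mixture(gen_dwell_times(0.55, 0.77, 8.2, 1e5, dt = 1),
                                  dt = 1)
  fast <- runif(1e5) < 0.55
  cont <- ifelse(fast, rexp(1e5, 1 / 0.77), rexp(1e5, 1 / 8.2))
  nearly_uncensored <- fit_exponential_mixture(cont, dt = 0.001)
  expect_lt(abs(disc$tau2 / nearly_uncensored$tau2 - 1), 0.02)
})

test_that("energy estimators evaluate their closed forms", {
  expect_equal(delta_g_diff(0.5, 13)$value, -3.26, tolerance = 0.005)
  expect_equal(delta_g_diff(0.9, 9)$value, -2.30, tolerance = 0.005)
  expect_equal(delta_g_diff(3, 3)$value, 0)
  # antisymmetry
  expect_equal(delta_g_diff(0.5, 13)$value + delta_g_diff(13, 0.5)$value, 0)
  expect_equal(delta_g_asso(830, 830)$value, 0)
  expect_equal(delta_g_asso(1000, 100)$value, -2.303, tolerance = 1e-3)
  expect_equal(delta_g_asso(22161, 830)$value, -3.28, tolerance = 0.005)
  expect_equal(round(bound_concentration(95, 2)), 22161)
  expect_equal(bound_concentration(100, 1), 10000)
  expect_equal(round(bound_concentration(95, 1)), 11080)
  expect_equal(oligomer_energy(n_s1 = 20, n_s2 = 20)$value, 0)
  expect_equal(oligomer_energy(n_s1 = 10, n_s2 = 10 * exp(2))$value, -2)
  expect_equal(oligomer_energy(n_s1 = 10, n_s2 = 74)$value, -2.00, tolerance = 0.005)
  expect_true(oligomer_energy(n_s1 = 0, n_s2 = 5)$inaccessible)
  expect_equal(barrier_height(10, 1e9)$value, 23.03, tolerance = 0.005)
  expect_equal(barrier_height(10, 1e10)$value, 25.33, tolerance = 0.005)
  expect_equal(barrier_height(1 / 1e9, 1e9)$value, 0)
})
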