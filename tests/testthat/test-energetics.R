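test_that("OLS is exact on noiseless polynomial data", {
  ser <- mismatch_series(c(14, 16, 18, 20), value = NA)
  ser$value <- 2 * ser$u0_sq_A2 + 1
  fit <- suppressWarnings(fit_vs_mismatch_sq(ser))  # exact fit: lm warns
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  serd <- mismatch_series(c(14, 16, 18, 20), value = 0.55)
  fd <- suppressWarnings(fit_diffusion_vs_mismatch(serd))
  expect_equal(fd$slope, 0, tolerance = 1e-12)
  expect_equal(fd$intercept, 0.55, tolerance = 1e-12)
  expect_error(fit_vs_mismatch_sq(ser[1:2, ]), "3 points")
})

test_that("mismatch series derives u0 from the thickness model", {
  ser <- mismatch_series(c(14, 16, 18, 20), value = 1:4)
  expect_equal(ser$u0_A, c(2.3, 0.6333333, 1.0333333, 2.7), tolerance = 1e-6)
  expect_equal(ser$u0_sq_A2, ser$u0_A^2)
})

test_that("reference tables reproduce the printed zero-mismatch intercepts", {
  en <- aqpz_reference_energies()
  kin <- aqpz_reference_kinetics()
  fd <- fit_vs_mismatch_sq(mismatch_series(en$chain_length, en$dG_diff))
  expect_lt(abs(fd$intercept - (-2.3)), 0.1)
  fa <- fit_vs_mismatch_sq(mismatch_series(en$chain_length, en$dG_asso))
  expect_lt(abs(fa$intercept - (-6.9)), 0.1)
  fD <- fit_diffusion_vs_mismatch(mismatch_series(kin$chain_length, kin$D_U))
  expect_lt(abs(fD$intercept - 0.7), 0.1)
})

test_that("dwell-time table feeds through to the printed energy column", {
  kin <- aqpz_reference_kinetics()
  en <- aqpz_reference_energies()
  dg <- mapply(function(t1, t2) delta_g_diff(t1, t2)$value, kin$tau1, kin$tau2)
  se <- mapply(function(t1, t2, s1, s2) delta_g_diff(t1, t2, s1, s2)$se,
               kin$tau1, kin$tau2, kin$tau1_se, kin$tau2_se)
  expect_true(all(abs(dg - en$dG_diff) <= pmax(en$dG_diff_se, se) + 0.06))
  fd <- fit_vs_mismatch_sq(mismatch_series(kin$chain_length, dg))
  expect_lt(abs(fd$intercept - (-2.3)), 0.15)
})

test_that("intercept recovery is unbiased on simulated diffusion series", {
  set.seed(20)
  ints <- replicate(500, {
    ser <- mismatch_series(c(14, 16, 18, 20), value = NA)
    ser$value <- 0.7 - 0.09 * ser$u0_A + rnorm(4, 0, 0.02)
    fit_diffusion_vs_mismatch(ser)$intercept
  })
  expect_lt(abs(median(ints) - 0.7), 0.03)
})

test_that("intercept standard error shrinks as 1/sqrt(n)", {
  set.seed(21)
  se_of <- function(reps) {
    ser <- mismatch_series(rep(c(14, 16, 18, 20), reps), value = NA)
    ser$value <- -2.3 - 0.13 * ser$u0_sq_A2 + rnorm(nrow(ser), 0, 0.2)
    fit_vs_mismatch_sq(ser)$intercept_se
  }
  expect_gt(se_of(2) / se_of(8), 1.6)   # expect ~2 for a 4x sample increase
})

test_that("contacts per bound molecule combine the two intercepts", {
  expect_equal(interactions_per_bound_molecule(-6.9, -2.3)$value, 3)
  expect_equal(interactions_per_bound_molecule(-4, -4)$value, 1)
  expect_equal(interactions_per_bound_molecule(-6.87, -2.33)$value, 2.95,
               tolerance = 0.005)
  expect_error(interactions_per_bound_molecule(-6.9, 0), "nonzero")
})

test_that("weighted OLS honors the provided errors", {
  ser <- mismatch_series(c(14, 16, 18, 20), value = c(-3.2, -2.5, -2.3, -3.2),
                         se = c(0.41, 0.27, 0.13, 0.25))
  fw <- fit_vs_mismatch_sq(ser, weighted = TRUE)
  fu <- fit_vs_mismatch_sq(ser, weighted = FALSE)
  expect_false(isTRUE(all.equal(fw$intercept, fu$intercept)))
  ser$se <- NA
  expect_error(fit_vs_mismatch_sq(ser, weighted = TRUE), "standard errors")
})
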