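b14 <- bilayer_spec(14)

test_that("no inclusions or zero mismatch give an identically zero field", {
  f <- solve_field_2d(list(), b14, h = b14$lambda_nm / 4)
  expect_true(all(f$u == 0))
  expect_equal(unname(deformation_energy(f)), c(0, 0, 0))
  f0 <- solve_field_2d(list(inclusion("cylinder", u0 = 0)), b14,
                       h = b14$lambda_nm / 4)
  expect_true(all(f0$u == 0))
})

test_that("deformation energy is translation invariant", {
  h <- b14$lambda_nm / 4
  e1 <- deformation_energy(solve_field_2d(list(inclusion("cylinder", c(0, 0), u0 = 2.3)),
                                          b14, h = h))
  e2 <- deformation_energy(solve_field_2d(list(inclusion("cylinder", c(3.3, -2.1), u0 = 2.3)),
                                          b14, h = h))
  expect_lt(abs(e2[["total"]] / e1[["total"]] - 1), 1e-6)
})

test_that("two inclusions 20 nm apart carry twice the isolated energy", {
  h <- b14$lambda_nm / 4
  single <- deformation_energy(
    solve_field_2d(list(inclusion("cylinder", c(0, 0), u0 = 2.3)), b14, h = h))
  half <- sqrt(AQPZ_FOOTPRINT_NM2 / pi) + 10
  pair <- deformation_energy(solve_field_2d(
    list(inclusion("cylinder", c(-half, 0), u0 = 2.3),
         inclusion("cylinder", c(half, 0), u0 = 2.3)), b14, h = h))
  expect_lt(abs(pair[["total"]] / (2 * single[["total"]]) - 1), 0.01)
})

test_that("field decays below 1% of u0 at the clamped outer edge", {
  f <- solve_field_2d(list(inclusion("cylinder", u0 = 2.3)), b14,
                      h = b14$lambda_nm / 4)
  edge <- c(f$u[3, ], f$u[, 3], f$u[nrow(f$u) - 2, ], f$u[, ncol(f$u) - 2])
  expect_lt(max(abs(edge)), 0.01 * 2.3)
})

test_that("a straight-boundary slice reproduces the 1D profile", {
  # giant cylinder: its locally straight boundary crosses a window domain
  R <- 300
  inc <- inclusion("cylinder", c(-R, 20), u0 = 2.3, radius = R)
  f <- solve_field_2d(list(inc), b14, h = b14$lambda_nm / 6,
                      domain = list(x = c(-2, 14), y = c(0, 40)))
  jmid <- which.min(abs(f$y - 20))
  prof2d <- f$u[, jmid]
  xfrom <- f$x - 0  # boundary at x = 0
  cf <- field_1d_closed_form(b14, 2.3, x = pmax(xfrom, 0))
  lipid <- xfrom > 0.2
  expect_lt(max(abs(prof2d[lipid] - cf$u[lipid])), 0.05 * 2.3)
})

test_that("energy is unchanged under grid halving within 2%", {
  e8 <- deformation_energy(solve_field_2d(list(inclusion("cylinder", u0 = 2.3)),
                                          b14, h = b14$lambda_nm / 8))
  e16 <- deformation_energy(solve_field_2d(list(inclusion("cylinder", u0 = 2.3)),
                                           b14, h = b14$lambda_nm / 16))
  expect_lt(abs(e16[["total"]] / e8[["total"]] - 1), 0.02)
})

test_that("compression and bending components sum to the total", {
  f <- solve_field_2d(list(inclusion("clover_leaf", u0 = 2.3)), b14,
                      h = b14$lambda_nm / 4)
  e <- deformation_energy(f)
  expect_equal(e[["total"]], e[["compression"]] + e[["bending"]])
  expect_gt(e[["compression"]], 0)
  expect_gt(e[["bending"]], 0)
})

test_that("a constant field on a plain grid has no bending energy", {
  nx <- 41; ny <- 41; h <- 0.3
  f <- structure(list(x = seq(0, by = h, length.out = nx),
                      y = seq(0, by = h, length.out = ny), h = h,
                      u = matrix(1.5, nx, ny),
                      inclusion_mask = matrix(FALSE, nx, ny),
                      inclusions = list(), bilayer = b14, residual = 0),
                 class = "deformation_field")
  e <- deformation_energy(f)
  expect_lt(e[["bending"]], 1e-10 * e[["compression"]])
})

test_that("geometry errors are caught", {
  expect_error(solve_field_2d(list(inclusion("cylinder", c(0, 0), u0 = 2),
                                   inclusion("cylinder", c(1, 0), u0 = 2)),
                              b14, h = b14$lambda_nm / 4), "overlap")
  expect_error(solve_field_2d(list(inclusion("cylinder", u0 = 2)), b14,
                              h = 2 * b14$lambda_nm), "too coarse")
  expect_error(deformation_energy(
    solve_field_2d(list(inclusion("cylinder", u0 = 2.3)), b14, h = b14$lambda_nm / 4),
    bilayer_spec(20)), "does not match")
})

test_that("pair potential is zero without mismatch and decays with distance", {
  pc0 <- pair_potential_curve(b14, c(1, 4, 8), u0 = 0, h = b14$lambda_nm / 4)
  expect_true(all(pc0$dG_total_kBT == 0))
  pc <- pair_potential_curve(b14, c(1, 8), h = b14$lambda_nm / 5)
  expect_lt(abs(pc$dG_total_kBT[pc$d_nm == 8]), abs(pc$dG_total_kBT[pc$d_nm == 1]))
  expect_equal(pc$dG_total_kBT,
               pc$dG_compression_kBT + pc$dG_bending_kBT, tolerance = 1e-8)
  expect_error(pair_potential_curve(b14, c(0.05, 1), h = b14$lambda_nm / 4),
               "below one grid cell")
  expect_error(pair_potential_curve(b14, c(4, 2), h = b14$lambda_nm / 4),
               "increasing")
})

test_that("local-configuration energies flag the zero-mismatch case and scale quadratically", {
  lc0 <- local_configuration_energies("cylinder", b14, u0 = 0,
                                      h = b14$lambda_nm / 4)
  expect_true(lc0$degenerate)
  expect_true(all(lc0$psi == 0))
  expect_true(all(is.na(lc0$psi_norm)))
  # linear solver: psi scales exactly quadratically in u0
  lc1 <- local_configuration_energies("cylinder", b14, u0 = 1.15,
                                      h = b14$lambda_nm / 4)
  lc2 <- local_configuration_energies("cylinder", b14, u0 = 2.3,
                                      h = b14$lambda_nm / 4)
  expect_equal(lc2$psi, 4 * lc1$psi, tolerance = 1e-8)
  expect_equal(lc1$psi_norm, lc2$psi_norm, tolerance = 1e-10)
})
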