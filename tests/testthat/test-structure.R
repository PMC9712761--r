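toy <- gen_toy_structure(belt = 30, seed = 2)

test_that("alignment is the identity for an already-aligned cylinder", {
  s <- normalize_structure(toy)
  expect_lt(attr(s, "rotation_angle") * 180 / pi, 0.5)
  expect_lt(max(abs(colMeans(as.matrix(s[, c("x", "y", "z")])))), 0.1)
})

test_that("a known rotation about x is recovered within 0.5 degrees", {
  s <- normalize_structure(rotate_atoms_x(toy, 37 * pi / 180))
  expect_lt(abs(attr(s, "rotation_angle") * 180 / pi - 37), 0.5)
  th <- hydrophobic_thickness(unroll_surface(s))
  expect_lt(abs(th$l - 30), 1.5)
})

test_that("the C4 axis of a synthetic tetramer is found within 1 degree", {
  one <- gen_toy_structure(radius = 8, belt = 30, height = 50,
                           n_per_ring = 12, seed = 5)
  tet <- do.call(rbind, lapply(0:3, function(k) {
    d <- one
    ang <- k * pi / 2 + pi / 4
    d$x <- d$x + 12 * cos(ang); d$y <- d$y + 12 * sin(ang)
    d
  }))
  s <- normalize_structure(tet)
  expect_lt(attr(s, "rotation_angle") * 180 / pi, 1)
})

test_that("an isotropic cloud is ambiguous without an axis hint", {
  set.seed(2)
  cloud <- data.frame(resid = "LEU", resno = 1:5000, elety = "CA",
                      x = rnorm(5000), y = rnorm(5000), z = rnorm(5000))
  expect_error(normalize_structure(cloud), "ambiguous")
  expect_silent(normalize_structure(cloud, axis_hint = c(0, 0, 1)))
  expect_error(normalize_structure(toy[1:50, ]), "100 atoms")
})

test_that("an all-hydrophobic surface classifies fully hydrophobic", {
  allh <- gen_toy_structure(belt = 60, height = 60, seed = 3)
  m <- unroll_surface(normalize_structure(allh))
  cls <- m$class[!is.na(m$class)]
  expect_true(all(cls == "hydrophobic"))
})

test_that("belt thickness is recovered to within one pixel row", {
  for (belt in c(24, 30, 36)) {
    s <- normalize_structure(gen_toy_structure(belt = belt, seed = belt))
    th <- hydrophobic_thickness(unroll_surface(s))
    expect_lt(abs(th$l - belt), 1.01)
  }
})

test_that("all-hydrophilic structure yields zero thickness with a flag", {
  s <- normalize_structure(gen_toy_structure(belt = 0, seed = 1))
  th <- hydrophobic_thickness(unroll_surface(s))
  expect_equal(th$l, 0)
  expect_true(th$no_band)
})

test_that("aromatic girdles change the thickness by at most one pixel row", {
  s0 <- normalize_structure(gen_toy_structure(belt = 30, seed = 2))
  sg <- normalize_structure(gen_toy_structure(belt = 30, girdle = TRUE, seed = 2))
  l0 <- hydrophobic_thickness(unroll_surface(s0))$l
  lg <- hydrophobic_thickness(unroll_surface(sg))$l
  expect_lt(abs(lg - l0), 1.01)
})

test_that("thickness is invariant under rigid rotation about z", {
  s <- normalize_structure(toy)
  rotz <- s
  ang <- 53 * pi / 180
  x <- s$x * cos(ang) - s$y * sin(ang)
  rotz$y <- s$x * sin(ang) + s$y * cos(ang)
  rotz$x <- x
  rotz$r <- sqrt(rotz$x^2 + rotz$y^2)
  rotz$theta <- (atan2(rotz$y, rotz$x) * 180 / pi) %% 360
  l1 <- hydrophobic_thickness(unroll_surface(s))$l
  l2 <- hydrophobic_thickness(unroll_surface(rotz))$l
  expect_lt(abs(l1 - l2), 1.01)
})

test_that("halving the pixel size changes the thickness by < 5%", {
  s <- normalize_structure(toy)
  l1 <- hydrophobic_thickness(unroll_surface(s, dtheta = 2, dz = 1))$l
  l2 <- hydrophobic_thickness(unroll_surface(s, dtheta = 1, dz = 0.5))$l
  expect_lt(abs(l2 / l1 - 1), 0.05)
})

test_that("buried atoms are down-weighted by the exposure factor", {
  # add a buried hydrophilic core to a hydrophobic shell: classification of
  # the surface must stay hydrophobic because r << r_max is suppressed
  shell <- gen_toy_structure(belt = 60, height = 60, radius = 15, seed = 4)
  core <- gen_toy_structure(belt = 0, height = 60, radius = 5, seed = 5)
  core$resno <- core$resno + max(shell$resno)
  both <- rbind(shell, core)
  m <- unroll_surface(normalize_structure(both, axis_hint = c(0, 0, 1)))
  cls <- m$class[!is.na(m$class)]
  expect_gt(mean(cls == "hydrophobic"), 0.95)
})

test_that("PDB round trip through bio3d preserves the structure", {
  f <- tempfile(fileext = ".pdb")
  gen_toy_structure(belt = 30, seed = 6, file = f)
  at <- read_structure(f)
  expect_gt(nrow(at), 900)
  th <- structure_thickness(at)
  expect_lt(abs(th$l - 30), 1.5)
  unlink(f)
})

test_that("angular sector restriction measures an interface face", {
  s <- normalize_structure(toy)
  lsec <- hydrophobic_thickness(unroll_surface(s, theta_range = c(0, 90)))$l
  lfull <- hydrophobic_thickness(unroll_surface(s))$l
  expect_lt(abs(lsec - lfull), 1.5)   # uniform toy: sector equals full surface
})
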