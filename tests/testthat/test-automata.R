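test_that("identical parameters and seed give identical trajectories", {
  p <- automaton_params(dims = c(24, 24), n_sweeps = 50, seed = 5)
  t1 <- run_automaton(p)
  t2 <- run_automaton(p)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$occupancy, t2$occupancy)
  t3 <- run_automaton(automaton_params(dims = c(24, 24), n_sweeps = 50, seed = 6))
  expect_false(identical(t1$events, t3$events))
})

test_that("an empty reservoir and zero energies produce no associations", {
  p <- automaton_params(e_pp = 0, scale = 0, c_u = 0, dims = c(24, 24),
                        n_sweeps = 50, seed = 2)
  tr <- run_automaton(p, seed_block = 6)
  expect_equal(sum(tr$events$event == "association"), 0)
})

test_that("events change occupancy one site at a time with bond count 1..3", {
  p <- automaton_params(dims = c(24, 24), n_sweeps = 60, seed = 8)
  tr <- run_automaton(p)
  expect_true(all(tr$events$bonds %in% 1:3))
  # replay the event log from the initial state and recover the final grid
  occ <- matrix(0L, 24, 24); occ[tr$frozen] <- 1L
  for (k in seq_len(nrow(tr$events))) {
    e <- tr$events[k, ]
    expect_equal(occ[e$x, e$y], if (e$event == "association") 0L else 1L)
    occ[e$x, e$y] <- if (e$event == "association") 1L else 0L
  }
  expect_identical(occ, tr$occupancy)
})

test_that("stationary distribution matches Boltzmann enumeration on a 3x3 lattice", {
  psi <- 0.8 * psi_norm_reference("clover_leaf")
  bz <- toy_boltzmann_3x3(psi, e_pp = -1.2, c_u = 5e4)
  p <- suppressWarnings(automaton_params(e_pp = -1.2, scale = 0.8, c_u = 5e4,
                                         dims = c(3, 3), n_sweeps = 4e5, seed = 11))
  tr <- suppressWarnings(run_automaton(p, frozen = bz$frozen, record_every = 90))
  obs <- tabulate(tr$states + 1, nbins = 256)
  keep <- bz$p > 5 / sum(obs)
  expected <- bz$p[keep] * sum(obs)
  chi2 <- sum((obs[keep] - expected)^2 / expected)
  pval <- pchisq(chi2, df = sum(keep), lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("measured dwell-time ratio matches the Hamiltonian depth difference", {
  # frozen scaffold exposing one permanent 1-bond and one permanent 2-bond
  # site; dissociation rates are then pure barrier rates and
  # -ln(tau2/tau1) must equal the binding-depth difference of the two sites
  nx <- 7; ny <- 7
  frozen <- matrix(TRUE, nx, ny)
  init <- matrix(0L, nx, ny)
  init[3, 2:4] <- 1L; init[4, 4] <- 1L           # an L-shaped frozen arm
  s1 <- c(3, 6); s2 <- c(4, 3)                   # 1B site; 2B corner site
  frozen[s1[1], s1[2]] <- FALSE
  init[3, 5] <- 1L                               # bridge so s1 has one bond
  frozen[s2[1], s2[2]] <- FALSE
  p <- suppressWarnings(automaton_params(e_pp = -2.0, scale = 1.2, c_u = 2e4,
                                         dims = c(nx, ny), n_sweeps = 3e5, seed = 21))
  tr <- suppressWarnings(run_automaton(p, init = init, frozen = frozen))
  cm <- tr$complete_events
  d1 <- cm$dwell_sweeps[cm$x == s1[1] & cm$y == s1[2] & cm$bonds == 1]
  d2 <- cm$dwell_sweeps[cm$x == s2[1] & cm$y == s2[2] & cm$bonds == 2]
  expect_gt(length(d1), 200)
  expect_gt(length(d2), 200)
  measured <- -log(mean(d2) / mean(d1))
  # oracle: depth difference from the R-side Hamiltonian
  psi <- 1.2 * psi_norm_reference("clover_leaf")
  mu <- log(2e4 * 6.7^2 * 1e-6)
  base <- init
  st1 <- base; st1[s1[1], s1[2]] <- 1L
  st2 <- base; st2[s2[1], s2[2]] <- 1L
  oracle <- lattice_hamiltonian(st2, psi, -2.0, mu) -
    lattice_hamiltonian(st1, psi, -2.0, mu)
  se <- sqrt(1 / length(d1) + 1 / length(d2))
  expect_lt(abs(measured - oracle), 3 * se + 0.05)
})

test_that("mismatch compacts the simulated clusters", {
  # bonds per molecule as the compactness measure: large deformation scale
  # favors filled rectangles over ragged aggregates
  compactness <- function(sc, seed) {
    p <- automaton_params(e_pp = -2.8, c_u = 100, scale = sc, dims = c(48, 48),
                          n_sweeps = 2000, seed = seed)
    tr <- run_automaton(p, seed_block = 10)
    occ <- tr$occupancy
    bonds <- sum(occ[-nrow(occ), ] * occ[-1, ]) + sum(occ[, -ncol(occ)] * occ[, -1])
    bonds / sum(occ)
  }
  loose <- mean(vapply(1:3, function(s) compactness(0, 30 + s), 0))
  compact <- mean(vapply(1:3, function(s) compactness(4, 40 + s), 0))
  expect_gt(compact, loose)
})

test_that("automaton kinetics require events of both classes", {
  p <- automaton_params(e_pp = 0, scale = 0, c_u = 0, dims = c(24, 24),
                        n_sweeps = 10, seed = 3)
  tr <- run_automaton(p, seed_block = 6)
  expect_error(measure_automaton_kinetics(tr), "zero complete events")
})
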