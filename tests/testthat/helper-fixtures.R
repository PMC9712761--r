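# shared fixtures built in code

# rotate an atom table about the x axis
rotate_atoms_x <- function(df, ang) {
  R <- matrix(c(1, 0, 0,
                0, cos(ang), -sin(ang),
                0, sin(ang), cos(ang)), 3, 3, byrow = TRUE)
  m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
  df
}

# enumerate the Boltzmann distribution of the 3x3 toy automaton with a frozen
# occupied centre, restricted to the communicating class of the empty start
toy_boltzmann_3x3 <- function(psi, e_pp, c_u, a = 6.7) {
  frozen <- matrix(FALSE, 3, 3); frozen[2, 2] <- TRUE
  free_idx <- which(!frozen)
  mu <- log(c_u * a^2 * 1e-6)
  state_of <- function(code) {
    m <- matrix(0L, 3, 3); m[2, 2] <- 1L
    m[free_idx] <- as.integer(bitwAnd(bitwShiftR(code, 0:7), 1L))
    m
  }
  nbc <- function(m, k) {
    i <- (k - 1) %% 3 + 1; j <- (k - 1) %/% 3 + 1
    s <- 0
    if (i > 1) s <- s + m[i - 1, j]; if (i < 3) s <- s + m[i + 1, j]
    if (j > 1) s <- s + m[i, j - 1]; if (j < 3) s <- s + m[i, j + 1]
    s
  }
  H <- numeric(256); adj <- vector("list", 256)
  for (code in 0:255) {
    m <- state_of(code)
    H[code + 1] <- lattice_hamiltonian(m, psi, e_pp, mu)
    nb <- vapply(free_idx, function(k) nbc(m, k), 0)
    adj[[code + 1]] <- which(nb >= 1 & nb <= 3)
  }
  reach <- rep(FALSE, 256); stack <- 0L; reach[1] <- TRUE
  while (length(stack)) {
    c0 <- stack[1]; stack <- stack[-1]
    for (b in adj[[c0 + 1]]) {
      c1 <- bitwXor(c0, bitwShiftL(1L, b - 1))
      if (!reach[c1 + 1]) { reach[c1 + 1] <- TRUE; stack <- c(stack, c1) }
    }
  }
  p <- exp(-(H - min(H[reach]))); p[!reach] <- 0
  list(p = p / sum(p), frozen = frozen)
}
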