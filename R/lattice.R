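#' Count 2x2 local configurations of a lattice state
#'
#' Slides a 2x2 window over the occupancy grid (zero-padded by one site on
#' every edge, so a lone molecule lies in exactly four windows) and counts the
#' windows containing exactly 1, 2, 3 or 4 occupied sites. These window
#' classes are the "local configurations" whose deformation energies
#' \eqn{\psi_1 \ldots \psi_4} drive array assembly.
#'
#' @param state Logical or 0/1 occupancy matrix.
#' @return Integer vector `c(n1, n2, n3, n4)`.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 1
#' count_local_configs(m) # one molecule: 4 windows of configuration 1
#' @export
count_local_configs <- function(state) {
  state <- pad_state(state)
  nr <- nrow(state); nc <- ncol(state)
  s <- state[-nr, -nc] + state[-1, -nc] + state[-nr, -1] + state[-1, -1]
  counts <- tabulate(s[s > 0], nbins = 4)
  stats::setNames(as.integer(counts), c("n1", "n2", "n3", "n4"))
}

pad_state <- function(state) {
  state <- (state != 0) * 1L
  rbind(0L, cbind(0L, state, 0L), 0L)
}

#' Membrane energy change of a lattice rearrangement
#'
#' Applies the local-configuration energy balance
#' \deqn{\Delta\psi = \delta n_1 \psi_1 + \delta n_2 \psi_2 +
#'   \delta n_3 \psi_3 + \delta n_4 \psi_4}
#' to a rearrangement between two occupancy states, where \eqn{\delta n_i} is
#' the gain or loss of windows of configuration i. The states may differ at
#' any number of sites (a bound-state change together with the arrival or
#' departure of the molecule from a distant membrane position is the
#' canonical two-site case).
#'
#' @param before,after Occupancy matrices of identical dimension.
#' @param psi Length-4 numeric vector of configuration energies (kBT), or a
#'   [local_configuration_energies()] object.
#' @return List of class `rearrangement_delta`: `delta_n` (integer, length 4)
#'   and `delta_psi` (kBT).
#' @examples
#' a <- matrix(0, 6, 6); a[1:3, 1:6] <- 1   # straight array edge
#' b <- a
#' a[6, 6] <- 1                             # molecule far away, unbound
#' b[4, 3] <- 1                             # molecule bound flat on the edge
#' delta_psi(a, b, c(1, 1.81, 3.01, 3.50))$delta_n  # the one-bond rearrangement
#' @export
delta_psi <- function(before, after, psi) {
  if (!identical(dim(before), dim(after))) {
    stop("before/after states differ in dimension", call. = FALSE)
  }
  if (all(before == after)) {
    return(structure(list(delta_n = stats::setNames(integer(4), c("n1", "n2", "n3", "n4")),
                          delta_psi = 0), class = "rearrangement_delta"))
  }
  dn <- count_local_configs(after) - count_local_configs(before)
  delta_psi_from_counts(dn, psi)
}

#' @rdname delta_psi
#' @param delta_n Integer vector of window-count changes
#'   \eqn{(\delta n_1, \ldots, \delta n_4)}.
#' @export
delta_psi_from_counts <- function(delta_n, psi) {
  psi <- as_psi(psi)
  stopifnot(length(delta_n) == 4)
  structure(list(delta_n = stats::setNames(as.integer(delta_n),
                                           c("n1", "n2", "n3", "n4")),
                 delta_psi = sum(delta_n * psi)),
            class = "rearrangement_delta")
}

#' @export
print.rearrangement_delta <- function(x, ...) {
  cat(sprintf("rearrangement: delta_n = {%s}, delta_psi = %.3f kBT\n",
              paste(x$delta_n, collapse = " "), x$delta_psi))
  invisible(x)
}

as_psi <- function(psi) {
  if (inherits(psi, "local_config_energies")) psi <- psi$psi
  stopifnot(is.numeric(psi), length(psi) == 4)
  psi
}

#' Lattice-gas Hamiltonian of an occupancy state
#'
#' Total configurational energy used by the assembly automaton:
#' \deqn{H = E_{PP} B + \sum_i n_i \psi_i - (\mu + 4\psi_1) N}
#' with B the number of occupied 4-neighbor pairs, \eqn{n_i} the 2x2 window
#' counts, N the number of molecules and \eqn{\mu = \ln(C_U a^2)} the
#' reservoir chemical potential. The \eqn{4\psi_1} term is the deformation
#' energy an isolated diffusing molecule carries in the window bookkeeping,
#' so that exchanging a molecule with the reservoir reproduces the membrane
#' energy of the full rearrangement (departure from isolation plus arrival in
#' the local configuration).
#'
#' @param state Occupancy matrix.
#' @param psi Length-4 configuration energies, kBT.
#' @param e_pp Direct protein-protein bond energy, kBT (negative attractive).
#' @param mu Reservoir chemical potential, kBT.
#' @return Energy in kBT.
#' @export
lattice_hamiltonian <- function(state, psi, e_pp, mu) {
  psi <- as_psi(psi)
  state <- (state != 0) * 1L
  nb <- count_bonds(state)
  n <- count_local_configs(state)
  e_pp * nb + sum(n * psi) - (mu + 4 * psi[1]) * sum(state)
}

# number of occupied 4-neighbor pairs
count_bonds <- function(state) {
  sum(state[-nrow(state), ] * state[-1, ]) + sum(state[, -ncol(state)] * state[, -1])
}
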