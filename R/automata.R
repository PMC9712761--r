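#' Parameters of the array-assembly automaton
#'
#' Bundles the energetic and geometric parameters of the stochastic lattice
#' simulator of membrane protein array assembly. Association and dissociation
#' moves exchange molecules with a reservoir of freely diffusing molecules at
#' 2D concentration `c_u`; each move is weighted by the direct bond energy
#' `e_pp` per protein-protein contact plus the membrane
#' local-configuration energy change (Eq. of [delta_psi()]) at strength
#' `scale` times the normalized energies `psi_norm`.
#'
#' The `scale` multiplier plays the role of the squared hydrophobic mismatch:
#' doubling the mismatch quadruples all configuration energies.
#'
#' @param e_pp Direct protein-protein bond energy, kBT (negative = attractive).
#' @param psi_norm Normalized local-configuration energies
#'   \eqn{\psi_i/\psi_1}; default the clover-leaf reference of
#'   [psi_norm_reference()].
#' @param scale Deformation-energy scale \eqn{\psi_1} in kBT (>= 0).
#' @param c_u Reservoir concentration of diffusers, molecules/um^2.
#' @param lattice_spacing Site spacing, nm.
#' @param dims Lattice dimensions `c(nx, ny)`. Smaller than 16 x 16 triggers
#'   an edge-effect warning.
#' @param n_sweeps Number of Monte-Carlo sweeps (one sweep = `nx*ny` single
#'   site updates).
#' @param seed Optional integer seed applied at the start of [run_automaton()].
#' @return Object of class `automaton_params`.
#' @export
automaton_params <- function(e_pp = -2.3, psi_norm = psi_norm_reference("clover_leaf"),
                             scale = 1, c_u = 830, lattice_spacing = 6.7,
                             dims = c(64, 64), n_sweeps = 200, seed = NULL) {
  stopifnot(length(psi_norm) == 4, scale >= 0, c_u >= 0, lattice_spacing > 0,
            length(dims) == 2, all(dims >= 2), n_sweeps >= 1)
  if (any(dims < 16)) {
    warning("lattice smaller than 16 x 16: open-boundary edge effects are not negligible")
  }
  if (!is.finite(e_pp) || any(!is.finite(psi_norm * scale))) {
    stop("non-finite energies", call. = FALSE)
  }
  structure(list(e_pp = e_pp, psi_norm = psi_norm, scale = scale, c_u = c_u,
                 lattice_spacing = lattice_spacing, dims = as.integer(dims),
                 n_sweeps = n_sweeps, seed = seed),
            class = "automaton_params")
}

#' @export
print.automaton_params <- function(x, ...) {
  cat(sprintf(
    "automaton_params: %d x %d, %d sweeps, E_PP = %.2f kBT, scale = %.2f, C_U = %.0f /um^2\n",
    x$dims[1], x$dims[2], x$n_sweeps, x$e_pp, x$scale, x$c_u))
  invisible(x)
}

# reservoir chemical potential mu = ln(C_U a^2), kBT
reservoir_mu <- function(c_u, lattice_spacing) {
  if (c_u <= 0) return(-Inf)
  log(c_u * (lattice_spacing^2 * 1e-6))
}

#' Run the array-assembly automaton
#'
#' Asynchronous single-site grand-canonical Metropolis dynamics: at each step
#' a random site is picked; insertion at an empty site or removal of a
#' molecule is proposed when the site's occupied-neighbor count is between 1
#' and 3 (interior 4-bond molecules are immobile, and the identical validity
#' rule for both directions preserves detailed balance). The move energy is
#' the direct bond term plus the membrane local-configuration change,
#' including the deformation energy the exchanged molecule carries at its
#' isolated reservoir position; acceptance is Metropolis
#' \eqn{\min(1, e^{-\Delta H})}. Runs are bit-reproducible for a fixed seed.
#'
#' @param params An [automaton_params()].
#' @param init Initial occupancy matrix (default: empty lattice with the seed
#'   block of `seed_block`).
#' @param seed_block Width of a frozen, always-occupied square block at the
#'   lattice center acting as a pre-existing array nucleus (0 disables).
#' @param frozen Optional logical matrix of immobilized sites (overrides
#'   `seed_block`).
#' @param record_every Record a compact state code every this many steps
#'   (small lattices only; used by equilibrium oracles). 0 disables.
#' @return Object of class `lattice_trajectory`: final `occupancy`, `events`
#'   data.frame (step, x, y, event, bonds), `complete_events` data.frame
#'   (x, y, start, end, bonds, dwell_sweeps), `mean_occupied`, the `params`,
#'   and recorded `states` codes if requested.
#' @examples
#' p <- automaton_params(dims = c(32, 32), n_sweeps = 20, seed = 1)
#' tr <- run_automaton(p)
#' tr
#' @export
run_automaton <- function(params, init = NULL, seed_block = 8, frozen = NULL,
                          record_every = 0) {
  stopifnot(inherits(params, "automaton_params"))
  nx <- params$dims[1]; ny <- params$dims[2]
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(frozen)) {
    frozen <- matrix(FALSE, nx, ny)
    if (seed_block > 0) {
      bi <- seq(floor((nx - seed_block) / 2) + 1, length.out = min(seed_block, nx))
      bj <- seq(floor((ny - seed_block) / 2) + 1, length.out = min(seed_block, ny))
      frozen[bi, bj] <- TRUE
    }
  }
  if (is.null(init)) {
    init <- matrix(0L, nx, ny)
    init[frozen] <- 1L
  }
  storage.mode(init) <- "integer"
  psi <- params$scale * params$psi_norm
  mu <- reservoir_mu(params$c_u, params$lattice_spacing)
  n_steps <- params$n_sweeps * nx * ny
  res <- .automaton_run_cpp(init, frozen, psi, params$e_pp,
                            if (is.finite(mu)) mu else -745, # exp underflows: no insertions
                            n_steps, as.integer(record_every))
  ev <- as.data.frame(res$events)
  names(ev) <- c("step", "x", "y", "event", "bonds")
  ev$event <- c("dissociation", "association")[ev$event + 1]
  cm <- as.data.frame(res$complete_events)
  names(cm) <- c("x", "y", "start", "end", "bonds")
  cm$dwell_sweeps <- (cm$end - cm$start) / (nx * ny)
  structure(list(occupancy = res$occupancy, events = ev, complete_events = cm,
                 mean_occupied = res$mean_occupied, states = res$states,
                 frozen = frozen, params = params),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf(
    "lattice_trajectory: %d x %d, %d sweeps, %d flips, %d complete events, <N> = %.1f\n",
    nrow(x$occupancy), ncol(x$occupancy), x$params$n_sweeps, nrow(x$events),
    nrow(x$complete_events), x$mean_occupied))
  invisible(x)
}

#' Sweep the deformation-energy scale and measure assembly energetics
#'
#' Runs the automaton at a series of deformation-energy scales (the proxy
#' for squared hydrophobic mismatch) and measures \eqn{\Delta G_{asso}} and
#' \eqn{\Delta G_{diff}} at each, mirroring how the mismatch dependence of
#' the experimental energies is mapped. Default conditions put the system
#' near array/reservoir coexistence (bond energy roughly balancing the
#' reservoir chemical potential) so that the array neither dissolves nor
#' fills the lattice across the sweep, the regime in which arrays and
#' diffusing molecules coexist at equilibrium; each condition is
#' burn-in-equilibrated before measuring.
#'
#' @param scales Deformation scales \eqn{\psi_1} to sweep, kBT.
#' @param e_pp Direct bond energy, kBT.
#' @param c_u Reservoir concentration, molecules/um^2.
#' @param psi_norm Normalized configuration energies.
#' @param dims Lattice dimensions.
#' @param burn_sweeps,measure_sweeps Equilibration and measurement lengths.
#' @param seed_block Frozen nucleus size.
#' @param seed Base seed; condition k uses `seed + k`.
#' @return data.frame with one row per scale: event counts, dwell times
#'   (sweeps), `dG_diff`, `dG_asso`, `c_b`.
#' @examples
#' \donttest{
#' automaton_scale_sweep(c(1, 4), measure_sweeps = 2000, seed = 1)
#' }
#' @export
automaton_scale_sweep <- function(scales = 1:4, e_pp = -2.8, c_u = 100,
                                  psi_norm = psi_norm_reference("clover_leaf"),
                                  dims = c(64, 64), burn_sweeps = 500,
                                  measure_sweeps = 20000, seed_block = 12,
                                  seed = 1) {
  rows <- lapply(seq_along(scales), function(k) {
    sc <- scales[k]
    pb <- automaton_params(e_pp = e_pp, psi_norm = psi_norm, scale = sc,
                           c_u = c_u, dims = dims, n_sweeps = burn_sweeps,
                           seed = seed + 1000L * k)
    burn <- run_automaton(pb, seed_block = seed_block)
    pm <- automaton_params(e_pp = e_pp, psi_norm = psi_norm, scale = sc,
                           c_u = c_u, dims = dims, n_sweeps = measure_sweeps,
                           seed = seed + 1000L * k + 1L)
    tr <- run_automaton(pm, init = burn$occupancy, frozen = burn$frozen)
    k2 <- suppressWarnings(measure_automaton_kinetics(tr))
    data.frame(scale = sc, n1 = k2$n1, n2 = k2$n2, tau1 = k2$tau1,
               tau2 = k2$tau2, dG_diff = k2$dG_diff,
               dG_diff_se = k2$dG_diff_se, c_b = k2$c_b, dG_asso = k2$dG_asso)
  })
  do.call(rbind, rows)
}

#' Kinetic and equilibrium energies measured from an automaton trajectory
#'
#' Extracts the complete association-to-dissociation events, classified by
#' bond count at association exactly as the experimental classifier (events
#' whose neighbor environment changed mid-event are discarded by the
#' simulator), fits the one-bond and two-bond dwell-time distributions, and
#' derives
#' \itemize{
#'   \item \eqn{\Delta G_{diff} = -\ln(\tau_2/\tau_1)} from the fitted mean
#'     dwells (sweeps), and
#'   \item \eqn{\Delta G_{asso} = -\ln(C_B/C_U)} from the time-averaged bound
#'     density \eqn{C_B} and the reservoir concentration.
#' }
#'
#' @param traj A [run_automaton()] trajectory.
#' @param min_events Minimum complete events per bond class before the dwell
#'   statistics are considered reliable; fewer triggers a warning.
#' @return List with `tau1`, `tau2` (sweeps), event counts, `dG_diff`,
#'   `dG_asso` (kBT, with delta-method standard errors) and the bound
#'   concentration `c_b` (molecules/um^2).
#' @export
measure_automaton_kinetics <- function(traj, min_events = 100) {
  stopifnot(inherits(traj, "lattice_trajectory"))
  cm <- traj$complete_events
  if (nrow(cm) == 0) stop("trajectory contains zero complete events", call. = FALSE)
  d1 <- cm$dwell_sweeps[cm$bonds == 1]
  d2 <- cm$dwell_sweeps[cm$bonds == 2]
  if (length(d1) < min_events || length(d2) < min_events) {
    warning(sprintf("few complete events (one-bond %d, two-bond %d): dwell statistics unreliable",
                    length(d1), length(d2)))
  }
  if (length(d1) == 0 || length(d2) == 0) {
    stop("need complete events of both bond classes", call. = FALSE)
  }
  tau1 <- mean(d1); tau2 <- mean(d2)
  # exponential dwell: se(log tau) ~ 1/sqrt(n)
  dg_diff <- -log(tau2 / tau1)
  dg_diff_se <- sqrt(1 / length(d1) + 1 / length(d2))
  a_um2 <- traj$params$lattice_spacing^2 * 1e-6
  n_sites <- prod(dim(traj$occupancy))
  c_b <- traj$mean_occupied / (n_sites * a_um2)
  dg_asso <- -log(c_b / traj$params$c_u)
  list(tau1 = tau1, tau2 = tau2,
       n1 = length(d1), n2 = length(d2),
       dG_diff = dg_diff, dG_diff_se = dg_diff_se,
       c_b = c_b, dG_asso = dg_asso)
}
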