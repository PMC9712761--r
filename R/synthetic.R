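#' Draw frame-discretized dwell times from a two-exponential mixture
#'
#' Emulates the observation process of bound-state dwell times: underlying
#' durations are drawn from
#' \eqn{c_1 Exp(\tau_1) + (1-c_1) Exp(\tau_2)} and discretized to whole
#' frames (ceiling, minimum one frame), which is exactly the censoring the
#' mixture fitter inverts.
#'
#' @param c1 Fast-component fraction in [0, 1].
#' @param tau1,tau2 Time constants, s.
#' @param n Number of events.
#' @param dt Frame interval, s.
#' @param seed Optional integer seed.
#' @return Numeric vector of dwell times (multiples of `dt`).
#' @examples
#' gen_dwell_times(0.55, 0.77, 8.2, n = 10, dt = 1, seed = 1)
#' @export
gen_dwell_times <- function(c1, tau1, tau2, n, dt = 1, seed = NULL) {
  stopifnot(c1 >= 0, c1 <= 1, tau1 > 0, tau2 > 0, n > 0)
  if (!is.null(seed)) set.seed(seed)
  fast <- stats::runif(n) < c1
  t <- ifelse(fast, stats::rexp(n, 1 / tau1), stats::rexp(n, 1 / tau2))
  pmax(1, ceiling(t / dt)) * dt
}

#' Simulate a height-spectroscopy trace of diffusing membrane proteins
#'
#' Emulates fixed-position AFM height spectroscopy: point particles diffuse
#' by 2D Brownian motion at density `c_u` in a periodic box around the
#' detection point; whenever a particle's cross-section disc (area
#' `a_protein`) covers the detection point the trace reads the event height
#' (drawn uniformly in `event_height`, per event), plus Gaussian baseline
#' noise everywhere.
#'
#' @param d Diffusion coefficient, um^2/s.
#' @param c_u 2D concentration of diffusers, molecules/um^2.
#' @param a_protein Protein cross-section area, nm^2.
#' @param rate Sampling rate, samples/s.
#' @param duration Trace duration, s.
#' @param noise_sd Baseline noise standard deviation, nm.
#' @param event_height Height band of diffusion events, nm (length 2).
#' @param box_factor Periodic box side in units of the detection diameter.
#' @param seed Optional integer seed.
#' @return Object of class `height_trace`: list with `z` (nm), `rate`,
#'   `duration`, and the ground-truth `truth` (per-sample occupancy flag and
#'   the generator parameters).
#' @examples
#' tr <- gen_height_trace(0.59, 830, rate = 1e5, duration = 0.05, seed = 1)
#' @export
gen_height_trace <- function(d, c_u, a_protein = AQPZ_FOOTPRINT_NM2,
                             rate = 1e6, duration = 1, noise_sd = 0.1,
                             event_height = c(1.0, 1.5), box_factor = 20,
                             seed = NULL) {
  stopifnot(d > 0, c_u >= 0, a_protein > 0, rate > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate * duration)
  r_det <- sqrt(a_protein / pi)              # nm: disc covers the point
  box <- box_factor * 2 * r_det              # nm
  if (box < 4 * r_det) stop("box too small for the detection geometry", call. = FALSE)
  n_part <- round(c_u * (box * 1e-3)^2)      # box in um
  if (c_u > 0 && n_part == 0) {
    stop("box too small to hold a single particle at this concentration; increase box_factor",
         call. = FALSE)
  }
  z <- stats::rnorm(n, 0, noise_sd)
  occupied <- rep(FALSE, n)
  if (n_part > 0) {
    step_sd <- sqrt(2 * d * 1e6 / rate)      # nm per axis per sample
    for (p in seq_len(n_part)) {
      px <- cumsum(c(stats::runif(1, -box / 2, box / 2), stats::rnorm(n - 1, 0, step_sd)))
      py <- cumsum(c(stats::runif(1, -box / 2, box / 2), stats::rnorm(n - 1, 0, step_sd)))
      # wrap into the periodic box centred on the detection point
      px <- (px + box / 2) %% box - box / 2
      py <- (py + box / 2) %% box - box / 2
      occupied <- occupied | (px^2 + py^2 <= r_det^2)
    }
    # per-event height: uniform in the band, constant within an event
    r <- rle(occupied)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      z[starts[k]:ends[k]] <- z[starts[k]:ends[k]] +
        stats::runif(1, event_height[1], event_height[2])
    }
  }
  structure(list(z = z, rate = rate, duration = duration,
                 truth = list(occupied = occupied, d = d, c_u = c_u,
                              a_protein = a_protein, noise_sd = noise_sd)),
            class = "height_trace")
}

#' @export
print.height_trace <- function(x, ...) {
  cat(sprintf("height_trace: %d samples at %.3g /s (%.3g s), occupancy %.3f%%\n",
              length(x$z), x$rate, x$duration,
              100 * mean(x$truth$occupied)))
  invisible(x)
}

#' Scripted occupancy movie with known association-dissociation events
#'
#' Builds a boolean per-frame lattice movie containing a static array block
#' plus scripted bound-state events of known class and dwell, the ground
#' truth for the event classifier.
#'
#' @param schedule data.frame with columns `x`, `y`, `start`, `frames`
#'   (first frame and length of each insertion). Events at the same site must
#'   not overlap.
#' @param dims Lattice dimensions `c(nx, ny)`.
#' @param n_frames Number of frames.
#' @param block Row/column extent of the static array block, as
#'   `list(x = c(i1, i2), y = c(j1, j2))`, or `NULL` for none.
#' @return List: `movie` (3D array), `truth` (the schedule with the bond
#'   class each event has against the static block and a `complete` flag for
#'   events not touching the movie boundaries).
#' @export
gen_occupancy_movie <- function(schedule, dims = c(16, 16), n_frames = 100,
                                block = list(x = c(1, 4), y = c(1, dims[2]))) {
  movie <- array(0L, c(dims, n_frames))
  if (!is.null(block)) {
    movie[block$x[1]:block$x[2], block$y[1]:block$y[2], ] <- 1L
  }
  if (nrow(schedule)) {
    key <- paste(schedule$x, schedule$y)
    for (s in split(schedule, key)) {
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= (s$start + s$frames)[-nrow(s)])) {
        stop("schedule conflict: overlapping or touching events at one site", call. = FALSE)
      }
    }
    for (k in seq_len(nrow(schedule))) {
      fr <- schedule$start[k]:(schedule$start[k] + schedule$frames[k] - 1)
      if (any(fr < 1 | fr > n_frames)) {
        stop("scheduled event outside the movie", call. = FALSE)
      }
      if (any(movie[schedule$x[k], schedule$y[k], fr] == 1L)) {
        stop("schedule conflict with existing occupancy", call. = FALSE)
      }
      movie[schedule$x[k], schedule$y[k], fr] <- 1L
    }
  }
  truth <- schedule
  if (nrow(truth)) {
    truth$end <- truth$start + truth$frames - 1
    truth$complete <- truth$start > 1 & truth$end < n_frames
    truth$bond_class <- vapply(seq_len(nrow(truth)), function(k) {
      nb <- neighbor_counts(movie, truth$x[k], truth$y[k], truth$start[k]) -
        0L # self not counted
      paste0(nb, "B")
    }, "")
  }
  list(movie = movie, truth = truth)
}

#' Toy cylindrical membrane-protein structure in PDB format
#'
#' Generates a cylindrical shell of pseudo-residues (one atom per residue)
#' with hydrophobic residue names inside a central belt, hydrophilic ones
#' outside, and optionally aromatic girdle rings at the belt edges -- the
#' ground-truth oracle for the hydrophobic-thickness scorer. This is a
#' synthetic stand-in structure, not a real protein.
#'
#' @param radius Cylinder radius, Angstrom.
#' @param belt Hydrophobic belt thickness, Angstrom (centered at z = 0).
#' @param height Total cylinder height, Angstrom.
#' @param n_per_ring Atoms per ring.
#' @param dz Ring spacing, Angstrom.
#' @param girdle Add TRP girdle rings just outside the belt edges.
#' @param jitter Positional noise sd, Angstrom.
#' @param file Optional path: write a PDB file there (via bio3d).
#' @param seed Optional integer seed.
#' @return data.frame with `resid`, `resno`, `elety`, `x`, `y`, `z`
#'   (invisibly writes `file` if given).
#' @examples
#' head(gen_toy_structure(belt = 30, seed = 1))
#' @export
gen_toy_structure <- function(radius = 15, belt = 30, height = 60,
                              n_per_ring = 24, dz = 1.5, girdle = FALSE,
                              jitter = 0.15, file = NULL, seed = NULL) {
  stopifnot(belt >= 0, belt <= height, radius > 0)
  if (!is.null(seed)) set.seed(seed)
  # rings offset by half a spacing so class boundaries fall between rings
  zs <- seq(-height / 2 + dz / 2, height / 2, by = dz)
  theta0 <- stats::runif(length(zs), 0, 2 * pi / n_per_ring)
  rows <- list()
  resno <- 0
  for (iz in seq_along(zs)) {
    z <- zs[iz]
    hydro <- abs(z) <= belt / 2 && belt > 0
    resid <- if (hydro) "LEU" else "SER"
    # aromatic girdle rings sit just outside the belt, on the hydrophilic side
    if (girdle && belt > 0 && !hydro && abs(z) - belt / 2 <= 1.5 * dz) resid <- "TRP"
    th <- theta0[iz] + 2 * pi * (seq_len(n_per_ring) - 1) / n_per_ring
    for (t in th) {
      resno <- resno + 1
      rows[[resno]] <- data.frame(
        resid = resid, resno = resno, elety = "CA",
        x = (radius + stats::rnorm(1, 0, jitter)) * cos(t),
        y = (radius + stats::rnorm(1, 0, jitter)) * sin(t),
        z = z + stats::rnorm(1, 0, jitter))
    }
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(file)) {
    bio3d::write.pdb(file = file, xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$resno, resid = atoms$resid,
                     elety = atoms$elety, chain = "A")
  }
  atoms
}
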