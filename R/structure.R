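#' Read a membrane-protein structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] that extracts heavy-atom ATOM
#' records (hydrogens are absent from crystal structures and excluded here)
#' as the plain atom table the surface scorer consumes.
#'
#' @param file Path to a PDB-format file.
#' @param chains Optional chain identifiers to keep.
#' @return data.frame with `resid`, `resno`, `elety`, `chain`, `x`, `y`, `z`.
#' @export
read_structure <- function(file, chains = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  at <- at[is.na(at$elesy) | at$elesy != "H", ]
  data.frame(resid = at$resid, resno = at$resno, elety = at$elety,
             chain = at$chain, x = at$x, y = at$y, z = at$z)
}

#' Center a structure and align its symmetry axis with z
#'
#' Translates the atom cloud to its centroid and rotates it so that the
#' symmetry axis coincides with the z axis. Without an explicit hint the
#' axis is taken from the coordinate covariance: for a rotationally
#' symmetric protein two principal variances are (nearly) equal and the
#' remaining distinct eigenvector is the symmetry axis.
#'
#' @param atoms Atom data.frame with `x`, `y`, `z` (e.g. [read_structure()]).
#' @param axis_hint Optional length-3 vector: the known symmetry axis in the
#'   input frame.
#' @param tol Relative eigenvalue separation below which the axis is
#'   considered ambiguous without a hint.
#' @return Object of class `aligned_structure`: the atom table with
#'   transformed coordinates plus cylindrical `r`, `theta` (degrees), and
#'   attributes `rotation` (3x3), `centroid`, `rotation_angle` (radians
#'   rotated).
#' @examples
#' s <- normalize_structure(gen_toy_structure(seed = 1))
#' attr(s, "rotation_angle")
#' @export
normalize_structure <- function(atoms, axis_hint = NULL, tol = 0.05) {
  if (nrow(atoms) < 100) stop("need at least 100 atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  xyz <- sweep(xyz, 2, centroid)
  if (is.null(axis_hint)) {
    ev <- eigen(stats::cov(xyz), symmetric = TRUE)
    lam <- ev$values
    # the distinct eigenvalue: the one farthest from the mean of the others
    sep <- vapply(1:3, function(k) {
      oth <- lam[-k]
      min(abs(lam[k] - oth)) / max(lam)
    }, 0)
    pairgap <- vapply(1:3, function(k) abs(diff(lam[-k])) / max(lam), 0)
    k <- which.min(pairgap)          # remaining pair most similar
    # floor the separation threshold at the sampling noise of the
    # covariance eigenvalues (~ sqrt(2/n) relative)
    tol_eff <- max(tol, 6 * sqrt(2 / nrow(atoms)))
    if (sep[k] < tol_eff) {
      stop("degenerate inertia tensor: symmetry axis ambiguous, supply axis_hint",
           call. = FALSE)
    }
    axis <- ev$vectors[, k]
  } else {
    axis <- axis_hint / sqrt(sum(axis_hint^2))
  }
  if (axis[3] < 0) axis <- -axis
  # rotation taking `axis` to e_z (Rodrigues)
  v <- c(axis[2], -axis[1], 0)       # axis x e_z
  s <- sqrt(sum(v^2)); cth <- axis[3]
  if (s < 1e-12) {
    R <- diag(3)
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  xyz <- xyz %*% t(R)
  out <- atoms
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out$r <- sqrt(out$x^2 + out$y^2)
  out$theta <- (atan2(out$y, out$x) * 180 / pi) %% 360
  attr(out, "rotation") <- R
  attr(out, "centroid") <- centroid
  attr(out, "rotation_angle") <- acos(pmin(1, pmax(-1, cth)))
  class(out) <- c("aligned_structure", "data.frame")
  out
}

# residue classification (config-overridable via arguments downstream)
residue_classes <- function() {
  list(hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "GLY", "CYS"),
       aromatic = c("TRP", "TYR"))
}

#' Unrolled-surface hydropathy scoring
#'
#' Unrolls the aligned structure surface onto a (theta, z) pixel grid and
#' scores each pixel for surface-exposed hydrophobic (R), hydrophilic (B)
#' and aromatic (G) residues:
#' \deqn{R_p = \sum_i \delta_{iR}\, e^{-(z_i - z_p)^2/\sigma_z^2}\,
#'   e^{-(r_i - r_{max})^2/\sigma_r^2}\, e^{-(\theta_i - \theta_p)^2/\sigma_\theta^2}}
#' over the atoms within the scoring region around the pixel, where
#' \eqn{r_{max}} is the radius of the most exposed atom in the region (so
#' buried residues are down-weighted) and the angular difference wraps
#' around. B and G use the hydrophilic/aromatic indicator instead. The
#' pixel class is the argmax of the three scores.
#'
#' @param s An [normalize_structure()] aligned structure.
#' @param dtheta,dz Pixel size: degrees and Angstrom (defaults 2 deg, 1 A).
#' @param region Scoring region extents `c(height_A, angle_deg)` around the
#'   pixel (defaults 10 A, 10 deg, i.e. +-5 of each).
#' @param sigmas Gaussian widths `c(sigma_z_A, sigma_r_A, sigma_theta_deg)`
#'   (defaults 3, 2, 5).
#' @param classes Residue classification list with components `hydrophobic`
#'   and `aromatic`; everything else is hydrophilic.
#' @param theta_range Angular sector to score, degrees `c(from, to)` in
#'   [0, 360]. Restricting the sector (e.g. the face a protomer exposes to
#'   its neighbor) yields the interface thickness instead of the
#'   membrane-exposed one.
#' @return Object of class `surface_map`: list with vectors `theta`, `z`,
#'   matrices `R`, `B`, `G` (theta x z), `class` (character matrix:
#'   "hydrophobic"/"hydrophilic"/"aromatic"/NA for empty regions), and the
#'   grid metadata.
#' @export
unroll_surface <- function(s, dtheta = 2, dz = 1, region = c(10, 10),
                           sigmas = c(3, 2, 5), classes = residue_classes(),
                           theta_range = c(0, 360)) {
  stopifnot(inherits(s, "aligned_structure"))
  half_z <- region[1] / 2; half_th <- region[2] / 2
  sz <- sigmas[1]; sr <- sigmas[2]; sth <- sigmas[3]
  theta_p <- seq(theta_range[1], theta_range[2] - dtheta, by = dtheta)
  z_p <- seq(floor(min(s$z)), ceiling(max(s$z)), by = dz)
  nt <- length(theta_p); nz <- length(z_p)
  R <- B <- G <- matrix(0, nt, nz)
  cls <- matrix(NA_character_, nt, nz)
  is_R <- s$resid %in% classes$hydrophobic
  is_G <- s$resid %in% classes$aromatic
  is_B <- !(is_R | is_G)
  for (it in seq_len(nt)) {
    dth <- abs(s$theta - theta_p[it])
    dth <- pmin(dth, 360 - dth)
    in_wedge <- dth <= half_th
    if (!any(in_wedge)) next
    wz <- s$z[in_wedge]; wr <- s$r[in_wedge]; wth <- dth[in_wedge]
    wR <- is_R[in_wedge]; wB <- is_B[in_wedge]; wG <- is_G[in_wedge]
    eth <- exp(-(wth / sth)^2)
    for (iz in seq_len(nz)) {
      dzv <- wz - z_p[iz]
      sel <- abs(dzv) <= half_z
      if (!any(sel)) next
      rmax <- max(wr[sel])
      wgt <- exp(-(dzv[sel] / sz)^2) * exp(-((wr[sel] - rmax) / sr)^2) * eth[sel]
      R[it, iz] <- sum(wgt[wR[sel]])
      B[it, iz] <- sum(wgt[wB[sel]])
      G[it, iz] <- sum(wgt[wG[sel]])
      cls[it, iz] <- c("hydrophobic", "hydrophilic", "aromatic")[
        which.max(c(R[it, iz], B[it, iz], G[it, iz]))]
    }
  }
  structure(list(theta = theta_p, z = z_p, R = R, B = B, G = G, class = cls,
                 dtheta = dtheta, dz = dz, region = region, sigmas = sigmas),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  tab <- table(factor(x$class, c("hydrophobic", "hydrophilic", "aromatic")))
  cat(sprintf("surface_map: %d x %d pixels (%g deg x %g A); %s\n",
              length(x$theta), length(x$z), x$dtheta, x$dz,
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Hydrophobic thickness from a classified surface map
#'
#' For every angular column the longest z-contiguous run of hydrophobic
#' pixels defines the hydrophobic band; the thickness is the band area
#' divided by the full angular width,
#' \eqn{l = A_{hydrophobic} / c_{surface}}, i.e. the mean band height in
#' Angstrom. Aromatic pixels are not part of the band (only hydrophobicity
#' vs hydrophilicity is considered for the thickness).
#'
#' @param map A [unroll_surface()] map.
#' @return Object of class `thickness_result`: `l` (Angstrom),
#'   `A_hydrophobic` (pixel area in theta.z units), `c_surface` (angular
#'   width), `band_per_column` (run length per column, Angstrom), and
#'   `no_band` flag when no hydrophobic pixel exists.
#' @examples
#' s <- normalize_structure(gen_toy_structure(belt = 30, seed = 1))
#' hydrophobic_thickness(unroll_surface(s))
#' @export
hydrophobic_thickness <- function(map) {
  stopifnot(inherits(map, "surface_map"))
  runs <- apply(map$class == "hydrophobic" & !is.na(map$class), 1, function(col) {
    if (!any(col)) return(0L)
    r <- rle(col)
    max(r$lengths[r$values])
  })
  a_hydro <- sum(runs) * map$dz * map$dtheta
  c_surface <- length(map$theta) * map$dtheta
  structure(list(l = a_hydro / c_surface,
                 A_hydrophobic = a_hydro, c_surface = c_surface,
                 band_per_column = runs * map$dz,
                 no_band = all(runs == 0)),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("thickness_result: l = %.2f A%s\n", x$l,
              if (x$no_band) " [no hydrophobic band]" else ""))
  invisible(x)
}

#' Hydrophobic thickness of a structure, end to end
#'
#' Convenience wrapper: align, unroll, classify, measure.
#'
#' @inheritParams normalize_structure
#' @inheritParams unroll_surface
#' @return A `thickness_result`.
#' @export
structure_thickness <- function(atoms, axis_hint = NULL, dtheta = 2, dz = 1,
                                region = c(10, 10), sigmas = c(3, 2, 5)) {
  s <- normalize_structure(atoms, axis_hint = axis_hint)
  hydrophobic_thickness(unroll_surface(s, dtheta = dtheta, dz = dz,
                                       region = region, sigmas = sigmas))
}
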