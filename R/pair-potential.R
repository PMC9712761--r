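#' Distance-dependent elastic pair potential between two inclusions
#'
#' Computes \eqn{\Delta G_{elas}(d) = G_{def}(d) - G_{def}(d_{ref})} for two
#' identical inclusions placed along the x axis at edge-to-edge distance d,
#' with the reference separation large enough (default 20 nm) that the two
#' deformation fields no longer couple. Compression and bending parts are
#' referenced separately and sum to the total.
#'
#' @param bilayer A [bilayer_spec()].
#' @param distances Sorted positive edge-to-edge distances, nm.
#' @param shape `"cylinder"` or `"clover_leaf"`.
#' @param u0 Boundary mismatch per leaflet, Angstrom.
#' @param h Grid spacing, nm (default `lambda/4`).
#' @param margin Clamped margin, nm (default 10 decay lengths).
#' @param reference Reference separation, nm (default 20).
#' @return A `data.frame` of class `pair_potential_curve` with columns
#'   `d_nm`, `dG_total_kBT`, `dG_compression_kBT`, `dG_bending_kBT`.
#' @examples
#' \donttest{
#' b <- bilayer_spec(14)
#' pc <- pair_potential_curve(b, distances = c(1, 4, 8), h = b$lambda_nm / 3)
#' }
#' @export
pair_potential_curve <- function(bilayer, distances,
                                 shape = c("cylinder", "clover_leaf"),
                                 u0 = NULL, h = bilayer$lambda_nm / 4,
                                 margin = 10 * bilayer$lambda_nm,
                                 reference = 20) {
  shape <- match.arg(shape)
  if (is.null(u0)) {
    u0 <- hydrophobic_mismatch(bilayer$l_bilayer, aqpz_hydrophobic_thickness(),
                               signed = TRUE)
  }
  if (any(diff(distances) <= 0) || any(distances <= 0)) {
    stop("distances must be positive and strictly increasing", call. = FALSE)
  }
  if (min(distances) < h) {
    stop(sprintf("smallest distance %.3f nm is below one grid cell (%.3f nm)",
                 min(distances), h), call. = FALSE)
  }
  if (u0 == 0) {
    out <- data.frame(d_nm = distances, dG_total_kBT = 0,
                      dG_compression_kBT = 0, dG_bending_kBT = 0)
    class(out) <- c("pair_potential_curve", "data.frame")
    return(out)
  }
  energy_at <- function(d) {
    ext <- inclusion(shape, u0 = u0)$extent
    half <- ext + d / 2
    pair <- list(inclusion(shape, center = c(-half, 0), u0 = u0),
                 inclusion(shape, center = c(half, 0), u0 = u0))
    f <- solve_field_2d(pair, bilayer, h = h, margin = margin,
                        allow_contact = TRUE)
    deformation_energy(f)
  }
  ref <- energy_at(reference)
  vals <- t(vapply(distances, energy_at, numeric(3)))
  out <- data.frame(d_nm = distances,
                    dG_total_kBT = vals[, "total"] - ref[["total"]],
                    dG_compression_kBT = vals[, "compression"] - ref[["compression"]],
                    dG_bending_kBT = vals[, "bending"] - ref[["bending"]])
  class(out) <- c("pair_potential_curve", "data.frame")
  out
}

#' Deformation energies of the four lattice local configurations
#'
#' Solves the 2D deformation field of a 2x2 block of lattice sites occupied by
#' 1, 2 (edge-adjacent), 3 (L-shaped) or 4 proteins, and returns the absolute
#' deformation energies \eqn{\psi_1 \ldots \psi_4} together with their
#' normalization \eqn{\psi_i / \psi_1}. Neighboring proteins on the lattice
#' are in contact, so the union of their cross-section masks forms the
#' Dirichlet region of each solve.
#'
#' In the crystalline array the protein cross-section is bounded by its
#' lattice cell: rigid neighbors are in contact, not interpenetrating. The
#' default geometry therefore uses contact packing -- a cylinder of radius
#' `lattice_spacing/2`, or a clover leaf with leaf radius and offset
#' `lattice_spacing/4` whose four protomer lobes point at the four bonded
#' neighbors -- rather than the free-standing footprint radius.
#'
#' @param shape `"cylinder"` or `"clover_leaf"`.
#' @param bilayer A [bilayer_spec()].
#' @param lattice_spacing Nearest-neighbor site distance, nm. Default 6.7
#'   (tetramer spacing of the p42(1)2 array: 9.5 nm / sqrt(2)).
#' @param u0 Boundary mismatch per leaflet, Angstrom. Default 2.3.
#' @param h Grid spacing, nm.
#' @param margin Clamped margin, nm.
#' @param contact_packing Use the lattice contact geometry above (default).
#'   `FALSE` falls back to the free-standing footprint-derived shapes, whose
#'   masks may then overlap at the default spacing.
#' @return Object of class `local_config_energies`: list with `psi` (kBT,
#'   length 4), `psi_norm`, `lattice_spacing`, `shape`, `u0` and a
#'   `degenerate` flag (TRUE when u0 = 0 and the normalization is undefined).
#' @examples
#' \donttest{
#' local_configuration_energies("cylinder", bilayer_spec(14))
#' }
#' @export
local_configuration_energies <- function(shape = c("cylinder", "clover_leaf"),
                                         bilayer = bilayer_spec(14),
                                         lattice_spacing = 6.7, u0 = 2.3,
                                         h = bilayer$lambda_nm / 5,
                                         margin = 10 * bilayer$lambda_nm,
                                         contact_packing = TRUE) {
  shape <- match.arg(shape)
  a <- lattice_spacing
  mk <- function(ctr) {
    if (!contact_packing) return(inclusion(shape, center = ctr, u0 = u0))
    if (shape == "cylinder") {
      inclusion(shape, center = ctr, u0 = u0, radius = a / 2)
    } else {
      inc <- inclusion(shape, center = ctr, u0 = u0, orientation = -pi / 4)
      inc$leaf_radius <- a / 4
      inc$leaf_offset <- a / 4
      inc$extent <- a / 2
      inc
    }
  }
  sites <- list(list(c(0, 0)),
                list(c(0, 0), c(a, 0)),
                list(c(0, 0), c(a, 0), c(0, a)),
                list(c(0, 0), c(a, 0), c(0, a), c(a, a)))
  # shared domain covering the full 2x2 block for all four solves, so the
  # discretization error is common mode and largely cancels in psi_norm
  ext <- mk(c(0, 0))$extent
  domain <- list(x = c(-margin - ext, a + ext + margin),
                 y = c(-margin - ext, a + ext + margin))
  psi <- vapply(sites, function(ss) {
    f <- solve_field_2d(lapply(ss, mk), bilayer, h = h, domain = domain,
                        allow_contact = TRUE)
    deformation_energy(f)[["total"]]
  }, 0)
  degenerate <- u0 == 0
  out <- list(psi = psi,
              psi_norm = if (degenerate) rep(NA_real_, 4) else psi / psi[1],
              lattice_spacing = lattice_spacing, shape = shape, u0 = u0,
              degenerate = degenerate)
  class(out) <- "local_config_energies"
  out
}

#' @export
print.local_config_energies <- function(x, ...) {
  cat(sprintf("local_config_energies (%s, u0 = %.2f A, a = %.2f nm)\n",
              x$shape, x$u0, x$lattice_spacing))
  cat("  psi      :", paste(sprintf("%.3f", x$psi), collapse = "  "), "kBT\n")
  if (x$degenerate) {
    cat("  psi_norm : undefined (u0 = 0)\n")
  } else {
    cat("  psi_norm :", paste(sprintf("%.2f", x$psi_norm), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Published normalized local-configuration energies
#'
#' Reference \eqn{\psi_{norm}} vectors for the cylindrical and clover-leaf
#' protein cross-section models, as obtained from numerical continuum solves
#' of the four local configurations.
#'
#' @param shape `"cylinder"` or `"clover_leaf"`.
#' @return Numeric length-4 vector \eqn{\psi_i/\psi_1}.
#' @export
psi_norm_reference <- function(shape = c("cylinder", "clover_leaf")) {
  shape <- match.arg(shape)
  if (shape == "cylinder") c(1.00, 1.81, 3.01, 3.50) else c(1.00, 2.06, 3.22, 4.10)
}
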