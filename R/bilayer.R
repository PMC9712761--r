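#' Bilayer mechanical specification
#'
#' Bundles the mechanical and geometric parameters of a fluid lipid bilayer
#' used throughout the elastic model: the area-stretch modulus \eqn{K_A}, the
#' bending modulus \eqn{\kappa_b}, and the hydrophobic thickness that enters
#' the compression term of the deformation energy.
#'
#' The elastic decay length \eqn{\lambda = (\kappa_b l^2 / K_A)^{1/4}} sets
#' the range over which a thickness perturbation relaxes; all grid defaults
#' elsewhere are expressed in units of \eqn{\lambda}.
#'
#' @param chain_length Integer number of carbons per acyl tail (12--24).
#' @param K_A Area-stretch modulus, kBT/nm^2. The default 58 kBT/nm^2
#'   (about 0.24 N/m) is typical of fluid PC bilayers and is kept identical
#'   across chain lengths, since monounsaturated PCs of different tail length
#'   have very similar stretch moduli.
#' @param kappa_b Bending modulus, kBT. Default 20 kBT.
#' @param l_bilayer Hydrophobic thickness in Angstrom. Defaults to the linear
#'   chain-length model of [bilayer_thickness()].
#' @param l Reference thickness (Angstrom) used in the compression term
#'   \eqn{K_A (u/l)^2}; defaults to `l_bilayer`.
#'
#' @return An object of class `bilayer_spec`: a list with fields
#'   `chain_length`, `K_A`, `kappa_b`, `l_bilayer`, `l` and the derived decay
#'   length `lambda_nm`.
#' @examples
#' b <- bilayer_spec(14)
#' b$lambda_nm
#' @export
bilayer_spec <- function(chain_length = 18, K_A = 58, kappa_b = 20,
                         l_bilayer = bilayer_thickness(chain_length),
                         l = l_bilayer) {
  if (!is.finite(K_A) || K_A <= 0) stop("K_A must be positive", call. = FALSE)
  if (!is.finite(kappa_b) || kappa_b <= 0) stop("kappa_b must be positive", call. = FALSE)
  if (!is.finite(l_bilayer) || l_bilayer <= 0) stop("l_bilayer must be positive", call. = FALSE)
  if (!is.finite(l) || l <= 0) stop("l must be positive", call. = FALSE)
  l_nm <- l / 10
  obj <- list(
    chain_length = as.integer(chain_length),
    K_A = K_A, kappa_b = kappa_b,
    l_bilayer = l_bilayer, l = l,
    lambda_nm = (kappa_b * l_nm^2 / K_A)^0.25
  )
  class(obj) <- "bilayer_spec"
  obj
}

#' @export
print.bilayer_spec <- function(x, ...) {
  cat(sprintf(
    "bilayer_spec: C%d  l = %.1f A  K_A = %.1f kBT/nm^2  kappa_b = %.1f kBT  lambda = %.2f nm\n",
    x$chain_length, x$l_bilayer, x$K_A, x$kappa_b, x$lambda_nm))
  invisible(x)
}

#' Hydrophobic bilayer thickness from acyl chain length
#'
#' Linear thickness model for monounsaturated PC bilayers, anchored at
#' 24 Angstrom for C14 and 34 Angstrom for C20 (about 1.7 Angstrom per
#' carbon over that range, consistent with the commonly quoted ~1.5 Angstrom
#' per additional carbon).
#'
#' @param chain_length Carbons per acyl tail; values outside 12--24 trigger an
#'   extrapolation warning.
#' @return Hydrophobic thickness in Angstrom.
#' @examples
#' bilayer_thickness(14) # 24
#' bilayer_thickness(20) # 34
#' @export
bilayer_thickness <- function(chain_length) {
  if (any(chain_length < 12 | chain_length > 24)) {
    warning("chain_length outside 12-24: extrapolating the linear thickness model")
  }
  24 + (chain_length - 14) * (10 / 6)
}

#' Hydrophobic mismatch per leaflet
#'
#' \eqn{u_0 = 0.5 |l_{bilayer} - l_{protein}|}: half the thickness difference,
#' i.e. the boundary deformation each leaflet must absorb at the protein-lipid
#' interface.
#'
#' @param l_bilayer,l_protein Hydrophobic thicknesses, Angstrom.
#' @param signed If `TRUE`, keep the sign of `l_bilayer - l_protein`
#'   (positive: bilayer thicker than the protein).
#' @return Mismatch u0 in Angstrom.
#' @examples
#' hydrophobic_mismatch(24, 28.6) # 2.3
#' @export
hydrophobic_mismatch <- function(l_bilayer, l_protein, signed = FALSE) {
  d <- 0.5 * (l_bilayer - l_protein)
  if (signed) d else abs(d)
}

#' Reference hydrophobic thickness of the AqpZ tetramer surface
#'
#' Membrane-exposed hydrophobic thickness of the AqpZ tetramer used as the
#' default protein thickness when converting chain lengths to mismatches.
#' @return Thickness in Angstrom (28.6).
#' @export
aqpz_hydrophobic_thickness <- function() 28.6

# area of one AqpZ tetramer in the p42(1)2 array, nm^2 (95 A cell, 2 tetramers)
AQPZ_FOOTPRINT_NM2 <- 45.125
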