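#' Reference single-molecule kinetics of AqpZ in C14-C20 bilayers
#'
#' Bundled reference dataset: per-bilayer dwell-time constants of the
#' ensemble two-exponential fit (with the tau1-fixed alternative in
#' `tau2_fixed`), diffusion coefficients and unbound 2D concentrations from
#' height spectroscopy, and the number of complete association-dissociation
#' events analyzed. Values are means +- s.e. over three biological
#' replicates per condition.
#'
#' @return data.frame with one row per bilayer (C14, C16, C18, C20).
#' @examples
#' aqpz_reference_kinetics()
#' @export
aqpz_reference_kinetics <- function() {
  data.frame(
    lipid = c("C14", "C16", "C18", "C20"),
    chain_length = c(14L, 16L, 18L, 20L),
    n_events = c(308L, 761L, 1096L, 288L),
    c1 = c(NA, NA, 0.55, NA),
    tau1 = c(0.5, 0.7, 0.9, 0.6),
    tau1_se = c(0.14, 0.10, 0.10, 0.10),
    tau2 = c(13, 9, 9, 15),
    tau2_se = c(3.3, 3.2, 1.1, 1.2),
    tau2_fixed = c(16, 8, 8, 17),
    tau2_fixed_se = c(4.9, 3.4, 1.7, 1.8),
    D_U = c(0.42, 0.64, 0.59, 0.48),
    D_U_se = c(0.05, 0.03, 0.03, 0.03),
    C_U = c(1110, 930, 830, 1160),
    C_U_se = c(39, 18, 10, 93))
}

#' Reference interaction energies of AqpZ in C14-C20 bilayers
#'
#' Bundled reference energies (kBT): the association energy of a free
#' molecule to the array and the one-to-two-bond strengthening energy, with
#' the common zero-mismatch extrapolations.
#'
#' @return data.frame with one row per bilayer.
#' @export
aqpz_reference_energies <- function() {
  data.frame(
    lipid = c("C14", "C16", "C18", "C20"),
    chain_length = c(14L, 16L, 18L, 20L),
    dG_asso = c(-5.4, -6.8, -6.6, -5.1),
    dG_asso_se = c(0.41, 0.61, 0.34, 0.56),
    dG_diff = c(-3.2, -2.5, -2.3, -3.2),
    dG_diff_se = c(0.41, 0.27, 0.13, 0.25),
    dG_pp_asso = -6.9,
    dG_pp_diff = -2.3)
}

#' Mismatch series: a measured quantity against hydrophobic mismatch
#'
#' Builds the regression table linking a per-bilayer measurement to the
#' hydrophobic mismatch computed from the linear bilayer-thickness model and
#' the protein's hydrophobic thickness.
#'
#' @param chain_length Integer vector of acyl chain lengths.
#' @param value Measured values (energies in kBT or D in um^2/s).
#' @param se Optional standard errors.
#' @param l_protein Protein hydrophobic thickness, Angstrom.
#' @return data.frame of class `mismatch_series` with `chain_length`,
#'   `u0_A`, `u0_sq_A2`, `value`, `se`.
#' @examples
#' en <- aqpz_reference_energies()
#' mismatch_series(en$chain_length, en$dG_diff, en$dG_diff_se)
#' @export
mismatch_series <- function(chain_length, value, se = NA,
                            l_protein = aqpz_hydrophobic_thickness()) {
  u0 <- hydrophobic_mismatch(bilayer_thickness(chain_length), l_protein)
  out <- data.frame(chain_length = chain_length, u0_A = u0, u0_sq_A2 = u0^2,
                    value = value, se = se)
  class(out) <- c("mismatch_series", "data.frame")
  out
}

#' Extrapolate an energy to zero hydrophobic mismatch
#'
#' Ordinary least squares of the measured energy on the squared mismatch
#' \eqn{u_0^2} (the elastic deformation energy is quadratic in the
#' mismatch); the intercept estimates the membrane-independent direct
#' protein-protein energy. Optionally weighted by 1/se^2.
#'
#' @param series A [mismatch_series()] (>= 3 points).
#' @param weighted Use 1/se^2 weights (default unweighted).
#' @return Object of class `mismatch_fit`: `intercept`, `slope`, their
#'   standard errors, `residuals`, and the underlying `stats::lm` fit.
#' @examples
#' en <- aqpz_reference_energies()
#' fit_vs_mismatch_sq(mismatch_series(en$chain_length, en$dG_diff))$intercept
#' @export
fit_vs_mismatch_sq <- function(series, weighted = FALSE) {
  ols_fit(series, series$u0_sq_A2, weighted)
}

#' Extrapolate the diffusion coefficient to zero mismatch
#'
#' OLS of D on the mismatch \eqn{u_0} (linear, not squared: the effective
#' membrane viscosity scales linearly with mismatch); the intercept is the
#' diffusion coefficient in a perfectly matching bilayer.
#'
#' @inheritParams fit_vs_mismatch_sq
#' @return A `mismatch_fit`.
#' @examples
#' k <- aqpz_reference_kinetics()
#' fit_diffusion_vs_mismatch(mismatch_series(k$chain_length, k$D_U))$intercept
#' @export
fit_diffusion_vs_mismatch <- function(series, weighted = FALSE) {
  ols_fit(series, series$u0_A, weighted)
}

ols_fit <- function(series, x, weighted) {
  if (nrow(series) < 3) stop("need at least 3 points to fit", call. = FALSE)
  df <- data.frame(x = x, y = series$value)
  w <- if (weighted) {
    if (any(is.na(series$se)) || any(series$se <= 0)) {
      stop("weighted fit needs positive standard errors", call. = FALSE)
    }
    1 / series$se^2
  } else NULL
  fit <- stats::lm(y ~ x, data = df, weights = w)
  cf <- summary(fit)$coefficients
  structure(list(intercept = cf[1, 1], slope = cf[2, 1],
                 intercept_se = cf[1, 2], slope_se = cf[2, 2],
                 residuals = stats::residuals(fit), lm = fit),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("mismatch_fit: intercept %.3f +- %.3f, slope %.4f +- %.4f\n",
              x$intercept, x$intercept_se, x$slope, x$slope_se))
  invisible(x)
}

#' Mean number of array contacts per bound molecule
#'
#' The ratio of the total association energy to the per-bond strengthening
#' energy, \eqn{\Delta G^0_{P-P(asso)} / \Delta G^0_{P-P(diff)}}, estimates
#' how many neighbor interactions an average array-bound molecule engages.
#'
#' @param dg_pp_asso,dg_pp_diff Zero-mismatch energies, kBT.
#' @param se_asso,se_diff Optional standard errors.
#' @return An `energy_estimate`-like list with `value` (dimensionless ratio)
#'   and propagated `se`.
#' @examples
#' interactions_per_bound_molecule(-6.9, -2.3) # 3
#' @export
interactions_per_bound_molecule <- function(dg_pp_asso, dg_pp_diff,
                                            se_asso = NA, se_diff = NA) {
  if (dg_pp_diff == 0) stop("dg_pp_diff must be nonzero", call. = FALSE)
  ratio <- dg_pp_asso / dg_pp_diff
  se <- if (is.na(se_asso) || is.na(se_diff)) NA_real_ else
    abs(ratio) * sqrt((se_asso / dg_pp_asso)^2 + (se_diff / dg_pp_diff)^2)
  list(value = ratio, se = se)
}
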