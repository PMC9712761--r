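#' Run an end-to-end analysis pipeline from a configuration
#'
#' Executes a declarative stage list -- synthetic-data generation, dwell-time
#' fitting, energy estimation, mismatch extrapolation -- and returns a report
#' in which every numeric result carries its stage name, parameters and
#' seed. Re-running an identical configuration and seed reproduces the
#' report exactly.
#'
#' Supported stage types and their parameter blocks:
#' \describe{
#'   \item{`gen_dwell_times`}{`c1`, `tau1`, `tau2`, `n`, `dt` -> dwell vector.}
#'   \item{`fit_mixture`}{`use` (name of a dwell stage), optional `fix_tau1`,
#'     `dt` -> mixture fit.}
#'   \item{`dg_diff`}{`use` (a fit stage) or explicit `tau1`, `tau2`.}
#'   \item{`dg_asso`}{`c_b`, `c_u`.}
#'   \item{`barrier`}{`tau`, `prefactor`.}
#'   \item{`extrapolate`}{`chain_length`, `value`, optional `se`,
#'     `x` = "u0sq" or "u0" -> OLS intercept/slope.}
#' }
#'
#' @param config Path to a YAML file or a list with fields `seed` and
#'   `stages` (a named list of stage blocks, each with a `type`).
#' @return Object of class `pipeline_report`: named list of stage results,
#'   each a list `(stage, type, params, value)`, plus `seed` and
#'   `package_version`.
#' @examples
#' cfg <- list(seed = 1, stages = list(
#'   dwells = list(type = "gen_dwell_times", c1 = 0.55, tau1 = 0.77,
#'                 tau2 = 8.2, n = 300, dt = 1),
#'   fit = list(type = "fit_mixture", use = "dwells", dt = 1),
#'   energy = list(type = "dg_diff", use = "fit")))
#' run_pipeline(cfg)$energy$value
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) stop("config error: unreadable YAML: ",
                                                conditionMessage(e), call. = FALSE))
  }
  if (!is.list(config) || is.null(config$stages)) {
    stop("config error: need a list with a `stages` block", call. = FALSE)
  }
  stages <- config$stages
  if (is.null(names(stages)) || any(names(stages) == "")) {
    stop("config error: every stage must be named", call. = FALSE)
  }
  # validate before executing anything
  known <- c("gen_dwell_times", "fit_mixture", "dg_diff", "dg_asso",
             "barrier", "extrapolate")
  for (nm in names(stages)) {
    ty <- stages[[nm]]$type
    if (is.null(ty) || !ty %in% known) {
      stop(sprintf("config error: stage '%s' has unknown type '%s'", nm,
                   if (is.null(ty)) "<missing>" else ty), call. = FALSE)
    }
    use <- stages[[nm]]$use
    if (!is.null(use) && !use %in% names(stages)[seq_len(match(nm, names(stages)) - 1)]) {
      stop(sprintf("config error: stage '%s' uses undefined earlier stage '%s'", nm, use),
           call. = FALSE)
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  data_env <- list()
  report <- list()
  for (nm in names(stages)) {
    st <- stages[[nm]]
    res <- switch(st$type,
      gen_dwell_times = {
        d <- gen_dwell_times(st$c1, st$tau1, st$tau2,
                             st$n_events %||% st$n,  # n_events: YAML-safe name
                             dt = st$dt %||% 1)
        data_env[[nm]] <- d
        list(n = length(d), mean_dwell_s = mean(d))
      },
      fit_mixture = {
        d <- data_env[[st$use]]
        if (is.null(d)) stop("config error: no dwell data in stage ", st$use, call. = FALSE)
        fit <- fit_exponential_mixture(d, dt = st$dt %||% 1,
                                       fix_tau1 = st$fix_tau1)
        data_env[[nm]] <- fit
        list(c1 = fit$c1, tau1 = fit$tau1, tau2 = fit$tau2,
             se = as.list(fit$se), loglik = fit$loglik)
      },
      dg_diff = {
        if (!is.null(st$use)) {
          fit <- data_env[[st$use]]
          est <- delta_g_diff(fit$tau1, fit$tau2, fit$se[["tau1"]], fit$se[["tau2"]])
        } else {
          est <- delta_g_diff(st$tau1, st$tau2)
        }
        list(value_kBT = est$value, se = est$se)
      },
      dg_asso = {
        est <- delta_g_asso(st$c_b, st$c_u)
        list(value_kBT = est$value, se = est$se)
      },
      barrier = {
        est <- barrier_height(st$tau, st$prefactor %||% 1e9)
        list(value_kBT = est$value)
      },
      extrapolate = {
        ser <- mismatch_series(unlist(st$chain_length), unlist(st$value),
                               if (is.null(st$se)) NA else unlist(st$se))
        fit <- if ((st$x %||% "u0sq") == "u0sq") fit_vs_mismatch_sq(ser)
               else fit_diffusion_vs_mismatch(ser)
        list(intercept = fit$intercept, intercept_se = fit$intercept_se,
             slope = fit$slope, slope_se = fit$slope_se)
      })
    report[[nm]] <- list(stage = nm, type = st$type,
                         params = st[setdiff(names(st), "type")],
                         value = res)
  }
  structure(c(report, list(seed = config$seed,
                           package_version = as.character(utils::packageVersion("mismatchkit")))),
            class = "pipeline_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  nms <- setdiff(names(x), c("seed", "package_version"))
  cat(sprintf("pipeline_report (%d stages, seed %s):\n", length(nms),
              if (is.null(x$seed)) "none" else x$seed))
  for (nm in nms) {
    v <- x[[nm]]$value
    num <- vapply(v, function(e) if (is.numeric(e) && length(e) == 1)
      sprintf("%.4g", e) else "...", "")
    cat(sprintf("  %s [%s]: %s\n", nm, x[[nm]]$type,
                paste(names(v), num, sep = " = ", collapse = ", ")))
  }
  invisible(x)
}

#' Reference-table replication pipeline
#'
#' The bundled end-to-end preset: feeds the reference per-bilayer dwell
#' times, concentrations and diffusion coefficients
#' ([aqpz_reference_kinetics()]) through the kinetic energy estimators and
#' the zero-mismatch extrapolations, reproducing the reference energy table
#' and the three intercepts.
#'
#' @return List with the per-bilayer energy table (`energies`), the three
#'   extrapolations (`dG_PP_diff`, `dG_PP_asso`, `D_U0`), the bound
#'   concentration used, and the contacts-per-molecule ratio.
#' @examples
#' rep <- replicate_reference_analysis()
#' rep$dG_PP_diff$intercept
#' @export
replicate_reference_analysis <- function() {
  kin <- aqpz_reference_kinetics()
  en <- aqpz_reference_energies()
  c_b <- bound_concentration(95, 2)
  energies <- data.frame(
    lipid = kin$lipid,
    dG_diff = mapply(function(t1, t2) delta_g_diff(t1, t2)$value,
                     kin$tau1, kin$tau2),
    dG_diff_se = mapply(function(t1, t2, s1, s2) delta_g_diff(t1, t2, s1, s2)$se,
                        kin$tau1, kin$tau2, kin$tau1_se, kin$tau2_se),
    dG_asso_eq3 = mapply(function(cu) delta_g_asso(c_b, cu)$value, kin$C_U))
  fit_diff <- fit_vs_mismatch_sq(
    mismatch_series(en$chain_length, en$dG_diff, en$dG_diff_se))
  fit_asso <- fit_vs_mismatch_sq(
    mismatch_series(en$chain_length, en$dG_asso, en$dG_asso_se))
  fit_d <- fit_diffusion_vs_mismatch(
    mismatch_series(kin$chain_length, kin$D_U, kin$D_U_se))
  list(energies = energies, c_b = c_b,
       dG_PP_diff = fit_diff, dG_PP_asso = fit_asso, D_U0 = fit_d,
       contacts = interactions_per_bound_molecule(
         fit_asso$intercept, fit_diff$intercept,
         fit_asso$intercept_se, fit_diff$intercept_se))
}
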