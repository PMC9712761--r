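#' One-dimensional leaflet deformation profile
#'
#' Solves the 1D reduction of the leaflet thickness-deformation problem: the
#' profile u(x) minimizing
#' \deqn{E[u] = \int_0^L \tfrac12\left[K_A (u/l)^2 + \kappa_b (u'')^2\right] dx}
#' subject to u(0) = u0, a natural (free-slope, u''(0) = 0) condition at the
#' inclusion contact, and u clamped to zero at the far end. One leaflet is
#' solved with monolayer moduli (half of `K_A` and `kappa_b`) and the energy
#' doubled for the mirror leaflet.
#'
#' The Euler-Lagrange equation \eqn{\kappa_b u'''' + (K_A/l^2) u = 0} admits
#' the decaying solution \eqn{u_0 e^{-\beta x}\cos\beta x} with
#' \eqn{\beta = (K_A/(4\kappa_b l^2))^{1/4}}, which serves as an analytic
#' check; see the package vignette.
#'
#' @param bilayer A [bilayer_spec()].
#' @param u0 Boundary mismatch per leaflet, Angstrom.
#' @param length Domain length in nm; must be at least 3 decay lengths
#'   (default 12).
#' @param n_nodes Number of grid nodes (>= 200).
#' @return Object of class `deformation_field_1d`: list with `x` (nm),
#'   `u` (Angstrom), `line_energy` (kBT per nm of boundary length) and its
#'   `compression`/`bending` components.
#' @examples
#' f <- solve_field_1d(bilayer_spec(14), u0 = 2.3)
#' f$line_energy
#' @export
solve_field_1d <- function(bilayer, u0, length = 12 * bilayer$lambda_nm,
                           n_nodes = 400) {
  stopifnot(inherits(bilayer, "bilayer_spec"))
  if (n_nodes < 200) stop("n_nodes must be >= 200", call. = FALSE)
  if (length < 3 * bilayer$lambda_nm) {
    stop(sprintf("domain length %.2f nm is shorter than 3 decay lengths (%.2f nm): ill-posed",
                 length, 3 * bilayer$lambda_nm), call. = FALSE)
  }
  h <- length / (n_nodes - 1)
  x <- seq(0, length, length.out = n_nodes)
  u0_nm <- u0 / 10
  l_nm <- bilayer$l / 10
  cK <- (bilayer$K_A / 2) / l_nm^2        # monolayer compression coefficient
  ck <- bilayer$kappa_b / 2               # monolayer bending coefficient

  if (u0 == 0) {
    u <- numeric(n_nodes)
    out <- list(x = x, u = u, h = h, bilayer = bilayer, u0 = u0,
                line_energy = 0, compression = 0, bending = 0)
    class(out) <- "deformation_field_1d"
    return(out)
  }

  # fixed nodes: node 1 at u0, last two nodes clamped to 0
  fixed <- rep(NA_real_, n_nodes)
  fixed[1] <- u0_nm
  fixed[(n_nodes - 1):n_nodes] <- 0
  free <- which(is.na(fixed))

  # second-difference rows at nodes 2..n-1
  rows <- 2:(n_nodes - 1)
  i <- rep(seq_along(rows), each = 3)
  j <- as.vector(t(cbind(rows - 1, rows, rows + 1)))
  v <- rep(c(1, -2, 1) / h^2, times = length(rows))
  L <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(length(rows), n_nodes))
  # trapezoid weights on the compression sum (half weight at the ends)
  wc <- rep(1, n_nodes); wc[c(1, n_nodes)] <- 0.5
  M <- h * (cK * Matrix::Diagonal(n_nodes, wc) + ck * Matrix::crossprod(L))
  M <- Matrix::forceSymmetric(M)

  uk <- fixed[-free]
  rhs <- -M[free, -free, drop = FALSE] %*% uk
  uf <- Matrix::solve(M[free, free], rhs)
  u_nm <- fixed
  u_nm[free] <- as.numeric(uf)

  lap <- as.numeric(L %*% u_nm)
  compression <- 2 * 0.5 * h * sum(cK * wc * u_nm^2)
  bending <- 2 * 0.5 * h * sum(ck * lap^2)

  out <- list(x = x, u = u_nm * 10, h = h, bilayer = bilayer, u0 = u0,
              line_energy = compression + bending,
              compression = compression, bending = bending)
  class(out) <- "deformation_field_1d"
  out
}

#' Closed-form 1D deformation profile and line energy
#'
#' Analytic minimizer of the 1D deformation functional on the half line with
#' u(0) = u0 and free contact slope: \eqn{u(x) = u_0 e^{-\beta x} \cos\beta x}
#' with \eqn{\beta = (K_A / (4 \kappa_b l^2))^{1/4}}, and total (two-leaflet)
#' line energy \eqn{\kappa_b \beta^3 u_0^2}.
#'
#' @inheritParams solve_field_1d
#' @param x Positions (nm) at which to evaluate the profile.
#' @return List with `beta` (1/nm), `u` (Angstrom, same length as `x`) and
#'   `line_energy` (kBT/nm).
#' @export
field_1d_closed_form <- function(bilayer, u0, x = NULL) {
  l_nm <- bilayer$l / 10
  beta <- (bilayer$K_A / (4 * bilayer$kappa_b * l_nm^2))^0.25
  u0_nm <- u0 / 10
  u <- if (is.null(x)) NULL else 10 * u0_nm * exp(-beta * x) * cos(beta * x)
  list(beta = beta, u = u,
       line_energy = bilayer$kappa_b * beta^3 * u0_nm^2)
}
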