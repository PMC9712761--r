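#' Two-dimensional leaflet deformation field around rigid inclusions
#'
#' Solves the discretized stationarity problem of the leaflet deformation
#' energy
#' \deqn{G_{def} = \tfrac12 \iint \left[K_A (u/l)^2 +
#'   \kappa_b (\nabla^2 u)^2 \right] dx\,dy}
#' on a regular square grid, with Dirichlet conditions u = u0 on the
#' protein-lipid boundary of every inclusion, a natural (free-slope) contact
#' condition, and the outer boundary clamped to zero. The deformation energy
#' is evaluated only over lipid area; the space occupied by proteins carries
#' no energy.
#'
#' Discretization: 5-point Laplacian rows squared into the 13-point biharmonic
#' quadratic form; stencil arms that cross an inclusion boundary are shortened
#' to the true crossing point (Shortley-Weller cut-boundary treatment) so the
#' curved Dirichlet boundary is honored to sub-grid accuracy, and compression
#' weights of cells cut by a boundary use the lipid area fraction
#' (supersampled). One leaflet is solved with monolayer moduli (half `K_A`,
#' half `kappa_b`) and the energy doubled for the mirror leaflet; the
#' free-slope condition is the natural boundary condition of the energy
#' functional and needs no explicit constraint. The minimization is a sparse
#' symmetric positive-definite solve (`Matrix` Cholesky).
#'
#' @param inclusions List of [inclusion()] objects (possibly empty).
#' @param bilayer A [bilayer_spec()].
#' @param h Grid spacing, nm. Default `lambda/4`.
#' @param margin Clamped outer margin beyond the inclusion bounding box, nm.
#'   Default 10 decay lengths.
#' @param domain Optional explicit domain as `list(x = c(min,max), y = c(min,max))`
#'   (nm); overrides `margin`.
#' @param allow_contact Permit touching/overlapping inclusion masks (their
#'   union becomes the Dirichlet region). Used for lattice local
#'   configurations where neighboring proteins are in contact; distinct
#'   free-standing inclusions must not overlap.
#' @param tol Relative residual tolerance of the linear solve.
#' @return Object of class `deformation_field`: list with node coordinates
#'   `x`, `y` (nm), matrix `u` (Angstrom; inclusion nodes filled with their
#'   u0 for display), logical `inclusion_mask`, `h`, the `bilayer`, the
#'   `inclusions`, and the solve residual.
#' @seealso [deformation_energy()], [pair_potential_curve()]
#' @export
solve_field_2d <- function(inclusions, bilayer, h = bilayer$lambda_nm / 4,
                           margin = 10 * bilayer$lambda_nm, domain = NULL,
                           allow_contact = FALSE, tol = 1e-6) {
  stopifnot(inherits(bilayer, "bilayer_spec"))
  if (inherits(inclusions, "inclusion")) inclusions <- list(inclusions)
  if (h > bilayer$lambda_nm / 2) {
    stop(sprintf("grid spacing %.3f nm too coarse for decay length %.3f nm",
                 h, bilayer$lambda_nm), call. = FALSE)
  }
  if (length(inclusions) >= 2 && !allow_contact) {
    for (a in seq_len(length(inclusions) - 1)) {
      for (b in (a + 1):length(inclusions)) {
        if (inclusions_overlap(inclusions[[a]], inclusions[[b]])) {
          stop("inclusions overlap", call. = FALSE)
        }
      }
    }
  }

  if (is.null(domain)) {
    if (length(inclusions) > 0) {
      cx <- vapply(inclusions, function(i) i$center[1], 0)
      cy <- vapply(inclusions, function(i) i$center[2], 0)
      ex <- vapply(inclusions, function(i) i$extent, 0)
      domain <- list(x = c(min(cx - ex) - margin, max(cx + ex) + margin),
                     y = c(min(cy - ex) - margin, max(cy + ex) + margin))
    } else {
      domain <- list(x = c(0, 20 * bilayer$lambda_nm),
                     y = c(0, 20 * bilayer$lambda_nm))
    }
  }
  x <- seq(domain$x[1], domain$x[2], by = h)
  y <- seq(domain$y[1], domain$y[2], by = h)
  nx <- length(x); ny <- length(y)

  field <- list(x = x, y = y, h = h, bilayer = bilayer,
                inclusions = inclusions)

  if (length(inclusions) == 0 ||
      all(vapply(inclusions, function(i) i$u0, 0) == 0)) {
    field$u <- matrix(0, nx, ny)
    field$inclusion_mask <- Reduce(`|`, lapply(inclusions, inclusion_mask, x = x, y = y),
                                   matrix(FALSE, nx, ny))
    field$u[field$inclusion_mask] <- 0
    field$residual <- 0
    class(field) <- "deformation_field"
    return(field)
  }

  ops <- field_operators(x, y, h, inclusions, bilayer)
  if (!any(ops$inc_mask)) {
    stop("no grid node falls inside any inclusion; refine the grid", call. = FALSE)
  }
  M <- ops$M
  b <- ops$b
  uf <- as.numeric(Matrix::solve(M, -b))
  res <- sqrt(sum((M %*% uf + b)^2))
  scale <- max(sqrt(sum(b^2)), 1e-12)
  if (!is.finite(res) || res / scale > tol) {
    stop(sprintf("elastic solver did not converge: residual %.3e", res), call. = FALSE)
  }

  u <- matrix(0, nx, ny)
  u[ops$unknown] <- uf
  # display values inside inclusions: their boundary u0
  for (inc in inclusions) u[inclusion_mask(inc, x, y)] <- inc$u0 / 10
  u[ops$dirichlet_extra] <- ops$dirichlet_value

  field$u <- u * 10
  field$inclusion_mask <- ops$inc_mask
  field$residual <- res
  class(field) <- "deformation_field"
  field
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf(
    "deformation_field: %d x %d nodes, h = %.3f nm, max|u| = %.2f A, %d inclusion nodes\n",
    length(x$x), length(x$y), x$h, max(abs(x$u)), sum(x$inclusion_mask)))
  invisible(x)
}

# Builds the quadratic energy form for one leaflet (doubled):
#   E(u) = h^2 [ cK/2 sum w_i u_i^2 + ck/2 sum_r (L_r u + g_r)^2 ] * 2
# over unknown (lipid, unclamped) nodes; returns M (Hessian), b (gradient
# constant), the L rows and boundary constants for energy re-evaluation.
field_operators <- function(x, y, h, inclusions, bilayer) {
  nx <- length(x); ny <- length(y)
  l_nm <- bilayer$l / 10
  cK <- (bilayer$K_A / 2) / l_nm^2
  ck <- bilayer$kappa_b / 2
  theta_min <- 0.1

  px <- as.vector(outer(x, rep(1, ny)))
  py <- as.vector(outer(rep(1, nx), y))
  inc_mask_v <- inside_any(inclusions, px, py)
  inc_mask <- matrix(inc_mask_v, nx, ny)

  ring <- matrix(FALSE, nx, ny)
  ring[c(1, 2, nx - 1, nx), ] <- TRUE
  ring[, c(1, 2, ny - 1, ny)] <- TRUE

  # lipid nodes within theta_min*h of an inclusion boundary are absorbed into
  # the Dirichlet set (prevents ill-conditioned cut arms)
  near <- matrix(FALSE, nx, ny)
  cand <- which(!inc_mask & !ring)
  ic <- ((cand - 1) %% nx) + 1
  jc <- ((cand - 1) %/% nx) + 1
  # only nodes with an inclusion node among their 4-neighbors can be that close
  nb_inc <- inc_mask[cbind(pmax(ic - 1, 1), jc)] | inc_mask[cbind(pmin(ic + 1, nx), jc)] |
            inc_mask[cbind(ic, pmax(jc - 1, 1))] | inc_mask[cbind(ic, pmin(jc + 1, ny))]
  dirichlet_value <- NULL
  for (k in which(nb_inc)) {
    node <- cand[k]
    p <- c(x[ic[k]], y[jc[k]])
    for (dxy in list(c(h, 0), c(-h, 0), c(0, h), c(0, -h))) {
      q <- p + dxy
      if (inside_any(inclusions, q[1], q[2])) {
        t <- boundary_crossing(inclusions, p, q)
        if (t < theta_min) { near[node] <- TRUE; break }
      }
    }
  }
  # value carried by absorbed nodes: u0 of the inclusion they hug
  dirichlet_extra <- which(near)
  dirichlet_value <- vapply(dirichlet_extra, function(node) {
    i <- ((node - 1) %% nx) + 1; j <- ((node - 1) %/% nx) + 1
    for (inc in inclusions) {
      if (inclusion_inside(inc, x[i] + h, y[j]) || inclusion_inside(inc, x[i] - h, y[j]) ||
          inclusion_inside(inc, x[i], y[j] + h) || inclusion_inside(inc, x[i], y[j] - h)) {
        return(inc$u0 / 10)
      }
    }
    0
  }, 0)

  fixed <- inc_mask | ring | near
  fixed_val <- matrix(0, nx, ny)
  for (inc in inclusions) fixed_val[inclusion_mask(inc, x, y)] <- inc$u0 / 10
  fixed_val[dirichlet_extra] <- dirichlet_value
  unknown <- which(!fixed)
  col_of <- rep(0L, nx * ny)
  col_of[unknown] <- seq_along(unknown)

  # compression weights: lipid area fraction of each unknown node's cell
  w <- rep(1, length(unknown))
  ui <- ((unknown - 1) %% nx) + 1
  uj <- ((unknown - 1) %/% nx) + 1
  touch <- nb_inc_any(inc_mask, ui, uj, nx, ny)
  if (any(touch)) {
    ss <- seq(-0.4, 0.4, by = 0.2)   # 5x5 supersampling of the cell
    for (k in which(touch)) {
      gx <- x[ui[k]] + ss * h
      gy <- y[uj[k]] + ss * h
      pts <- expand.grid(gx = gx, gy = gy)
      w[k] <- mean(!inside_any(inclusions, pts$gx, pts$gy))
    }
  }

  # Laplacian rows at interior unknown nodes, with cut arms
  rows_at <- which(!fixed & row(inc_mask) > 1 & row(inc_mask) < nx &
                   col(inc_mask) > 1 & col(inc_mask) < ny)
  trip_i <- integer(0); trip_j <- integer(0); trip_v <- numeric(0)
  g <- numeric(length(rows_at))
  # fast path: rows whose 4 neighbors are all unknown or ring (plain stencil)
  ri <- ((rows_at - 1) %% nx) + 1
  rj <- ((rows_at - 1) %/% nx) + 1
  nbW <- rows_at - 1; nbE <- rows_at + 1
  nbS <- rows_at - nx; nbN <- rows_at + nx
  plain <- !inc_mask[nbW] & !inc_mask[nbE] & !inc_mask[nbS] & !inc_mask[nbN] &
           !near[nbW] & !near[nbE] & !near[nbS] & !near[nbN]
  pr <- which(plain)
  if (length(pr)) {
    rid <- rep(pr, times = 5)
    cols <- c(col_of[nbW[pr]], col_of[nbE[pr]], col_of[nbS[pr]], col_of[nbN[pr]],
              col_of[rows_at[pr]])
    vals <- c(rep(1 / h^2, 4 * length(pr)), rep(-4 / h^2, length(pr)))
    keep <- cols > 0          # ring neighbors (value 0) drop out
    trip_i <- rid[keep]; trip_j <- cols[keep]; trip_v <- vals[keep]
  }
  for (k in which(!plain)) {
    node <- rows_at[k]
    p <- c(x[ri[k]], y[rj[k]])
    gk <- 0
    coef_self <- 0
    for (axis in 1:2) {
      arms <- if (axis == 1) list(c(-h, 0), c(h, 0)) else list(c(0, -h), c(0, h))
      th <- c(1, 1); bval <- c(NA_real_, NA_real_); nbn <- c(NA_integer_, NA_integer_)
      for (s in 1:2) {
        q <- p + arms[[s]]
        nb <- node + switch((axis - 1) * 2 + s, -1L, 1L, -nx, nx)
        if (inc_mask[nb] || near[nb]) {
          if (inc_mask[nb]) {
            th[s] <- max(boundary_crossing(inclusions, p, q), theta_min)
            bval[s] <- boundary_u0(inclusions, p, q, th[s])
          } else {            # absorbed near-boundary node: full arm, its value
            th[s] <- 1
            bval[s] <- fixed_val[nb]
          }
        } else {
          nbn[s] <- nb
        }
      }
      denom <- th[1] * th[2] * (th[1] + th[2]) * h^2 / 2
      for (s in 1:2) {
        coef <- th[3 - s] / denom
        if (is.na(bval[s])) {
          cc <- col_of[nbn[s]]
          if (cc > 0) {
            trip_i <- c(trip_i, k); trip_j <- c(trip_j, cc); trip_v <- c(trip_v, coef)
          }                  # else ring node, value 0
        } else {
          gk <- gk + coef * bval[s]
        }
      }
      coef_self <- coef_self - (th[1] + th[2]) / denom
    }
    cc <- col_of[node]
    trip_i <- c(trip_i, k); trip_j <- c(trip_j, cc); trip_v <- c(trip_v, coef_self)
    g[k] <- gk
  }
  L <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_v,
                            dims = c(length(rows_at), length(unknown)))
  # area-fraction quadrature on the bending rows as well
  wb <- sqrt(w[col_of[rows_at]])
  L <- Matrix::Diagonal(length(rows_at), wb) %*% L
  g <- wb * g

  W <- Matrix::Diagonal(length(unknown), w)
  M <- h^2 * (cK * W + ck * Matrix::crossprod(L))
  M <- Matrix::forceSymmetric(M)
  b <- h^2 * ck * as.numeric(Matrix::crossprod(L, g))

  list(M = M, b = b, L = L, g = g, w = w, unknown = unknown,
       inc_mask = inc_mask, fixed_val = fixed_val,
       dirichlet_extra = dirichlet_extra, dirichlet_value = dirichlet_value,
       cK = cK, ck = ck)
}

# any 4-neighbor (clamped to grid) inside an inclusion
nb_inc_any <- function(inc_mask, ii, jj, nx, ny) {
  inc_mask[cbind(pmax(ii - 1, 1), jj)] | inc_mask[cbind(pmin(ii + 1, nx), jj)] |
    inc_mask[cbind(ii, pmax(jj - 1, 1))] | inc_mask[cbind(ii, pmin(jj + 1, ny))]
}

# u0 of the inclusion whose boundary the arm p -> q crosses at fraction t
boundary_u0 <- function(inclusions, p, q, t) {
  pt <- p + min(t * 1.02, 1) * (q - p)
  for (inc in inclusions) {
    if (inclusion_inside(inc, pt[1], pt[2])) return(inc$u0 / 10)
  }
  # fall back: the inclusion containing q
  for (inc in inclusions) {
    if (inclusion_inside(inc, q[1], q[2])) return(inc$u0 / 10)
  }
  0
}

#' Deformation energy of a solved field
#'
#' Evaluates the two-leaflet deformation energy
#' \eqn{2 \times \tfrac12 \iint [ (K_A/2)(u/l)^2 + (\kappa_b/2)(\nabla^2 u)^2 ]}
#' over the lipid region of a [solve_field_2d()] field, using the same
#' cut-boundary operators as the solver, and reports the compression and
#' bending parts separately. Inclusion-covered area contributes nothing.
#'
#' @param field A `deformation_field`.
#' @param bilayer The [bilayer_spec()] the field was solved on (defaults to
#'   the one stored in the field). A different bilayer is a consistency error.
#' @return Named numeric vector `c(total, compression, bending)` in kBT.
#' @examples
#' b <- bilayer_spec(14)
#' f <- solve_field_2d(list(inclusion("cylinder", u0 = 2.3)), b, h = b$lambda_nm / 3)
#' deformation_energy(f)
#' @export
deformation_energy <- function(field, bilayer = field$bilayer) {
  stopifnot(inherits(field, "deformation_field"))
  if (!identical(unclass(bilayer)[c("K_A", "kappa_b", "l")],
                 unclass(field$bilayer)[c("K_A", "kappa_b", "l")])) {
    stop("bilayer does not match the one the field was solved on", call. = FALSE)
  }
  if (all(field$u == 0)) {
    return(c(total = 0, compression = 0, bending = 0))
  }
  h <- field$h
  l_nm <- bilayer$l / 10
  if (length(field$inclusions) == 0) {
    # plain grid: straight finite differences on the full field
    u <- field$u / 10
    nx <- nrow(u); ny <- ncol(u)
    lap <- (u[1:(nx - 2), 2:(ny - 1)] + u[3:nx, 2:(ny - 1)] +
            u[2:(nx - 1), 1:(ny - 2)] + u[2:(nx - 1), 3:ny] -
            4 * u[2:(nx - 1), 2:(ny - 1)]) / h^2
    compression <- h^2 * (bilayer$K_A / 2) / l_nm^2 * sum(u^2)
    bending <- h^2 * (bilayer$kappa_b / 2) * sum(lap^2)
    return(c(total = compression + bending, compression = compression,
             bending = bending))
  }
  ops <- field_operators(field$x, field$y, field$h, field$inclusions, bilayer)
  u <- as.vector(field$u / 10)[ops$unknown]
  lap <- as.numeric(ops$L %*% u + ops$g)
  compression <- h^2 * ops$cK * sum(ops$w * u^2)
  bending <- h^2 * ops$ck * sum(lap^2)
  c(total = compression + bending, compression = compression, bending = bending)
}
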