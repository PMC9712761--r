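#' Membrane inclusion geometry
#'
#' Describes the in-plane cross-section of a rigid membrane inclusion that
#' imposes a fixed thickness deviation `u0` on the surrounding leaflet.
#' Two shapes are supported: a cylinder (disc cross-section) and a
#' "clover leaf" built from four overlapping discs, mimicking a four-fold
#' symmetric tetramer cross-section.
#'
#' For the clover leaf the four disc centers sit on the diagonals at distance
#' equal to the disc radius from the inclusion center; the radius is solved
#' numerically so that the union area equals `area` (default: the 45.125 nm^2
#' tetramer footprint).
#'
#' @param shape `"cylinder"` or `"clover_leaf"`.
#' @param center Numeric length-2, inclusion center (nm).
#' @param u0 Boundary thickness deviation per leaflet, Angstrom (signed).
#' @param radius Cylinder radius in nm. Default derived from `area`.
#' @param area Footprint area in nm^2 used to derive default radii.
#' @param orientation Rotation of the shape about its center, radians.
#' @return Object of class `inclusion` with fields `shape`, `center`, `u0`,
#'   `radius` (cylinder) or `leaf_radius`/`leaf_offset` (clover), and
#'   `extent` (max distance from center to the boundary, nm).
#' @examples
#' inclusion("cylinder", c(0, 0), u0 = 2.3)
#' @export
inclusion <- function(shape = c("cylinder", "clover_leaf"), center = c(0, 0),
                      u0 = 2.3, radius = NULL, area = AQPZ_FOOTPRINT_NM2,
                      orientation = 0) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2, is.finite(u0))
  obj <- list(shape = shape, center = as.numeric(center), u0 = u0,
              orientation = orientation)
  if (shape == "cylinder") {
    obj$radius <- if (is.null(radius)) sqrt(area / pi) else radius
    obj$extent <- obj$radius
  } else {
    r <- clover_leaf_radius(area)
    obj$leaf_radius <- r
    obj$leaf_offset <- r           # disc centers at distance r along diagonals
    obj$extent <- 2 * r
  }
  class(obj) <- "inclusion"
  obj
}

#' @export
print.inclusion <- function(x, ...) {
  cat(sprintf("inclusion: %s at (%.2f, %.2f) nm, u0 = %.2f A, extent %.2f nm\n",
              x$shape, x$center[1], x$center[2], x$u0, x$extent))
  invisible(x)
}

# Disc radius for a 4-leaf clover (centers on diagonals at distance r) whose
# union area matches `area`. Adjacent disc centers are r*sqrt(2) apart, so the
# union area is 4*pi*r^2 minus four lens overlaps; closed form below.
clover_leaf_radius <- function(area) {
  # lens area of two discs radius r at distance r*sqrt(2):
  #   2 r^2 acos(sqrt(2)/2) - (sqrt(2)/2) r^2 sqrt(4 - 2)  =  (pi/2 - 1) r^2
  unit_area <- 4 * pi - 4 * (pi / 2 - 1)   # union area for r = 1
  sqrt(area / unit_area)
}

# TRUE for points (px, py) covered by the inclusion (vectorized).
inclusion_inside <- function(inc, px, py) {
  cx <- inc$center[1]; cy <- inc$center[2]
  if (inc$shape == "cylinder") {
    return((px - cx)^2 + (py - cy)^2 <= inc$radius^2)
  }
  r <- inc$leaf_radius; s <- inc$leaf_offset
  ang <- inc$orientation + (pi / 4 + (0:3) * pi / 2)
  m <- rep(FALSE, length(px))
  for (a in ang) {
    lx <- cx + s * cos(a); ly <- cy + s * sin(a)
    m <- m | ((px - lx)^2 + (py - ly)^2 <= r^2)
  }
  m
}

# TRUE for points covered by any inclusion in the list.
inside_any <- function(inclusions, px, py) {
  m <- rep(FALSE, length(px))
  for (inc in inclusions) m <- m | inclusion_inside(inc, px, py)
  m
}

# Logical mask of grid nodes covered by an inclusion.
# x, y: node coordinate vectors (nm). Returns matrix length(x) x length(y).
inclusion_mask <- function(inc, x, y) {
  px <- outer(x, rep(1, length(y)))
  py <- outer(rep(1, length(x)), y)
  matrix(inclusion_inside(inc, as.vector(px), as.vector(py)),
         length(x), length(y))
}

# Fractional position t in (0, 1] along p -> q at which the segment first
# enters the union of inclusions; q must be inside, p outside. Bisection on
# the inside predicate (shape agnostic).
boundary_crossing <- function(inclusions, p, q, iters = 30) {
  lo <- 0; hi <- 1
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pt <- p + mid * (q - p)
    if (inside_any(inclusions, pt[1], pt[2])) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# TRUE if two inclusions' covered regions intersect (coarse rasterized test).
inclusions_overlap <- function(a, b, h = 0.05) {
  gap <- sqrt(sum((a$center - b$center)^2)) - (a$extent + b$extent)
  if (gap > 0) return(FALSE)
  if (a$shape == "cylinder" && b$shape == "cylinder") return(TRUE)
  lim <- range(c(a$center[1] + c(-1, 1) * a$extent, b$center[1] + c(-1, 1) * b$extent))
  lim2 <- range(c(a$center[2] + c(-1, 1) * a$extent, b$center[2] + c(-1, 1) * b$extent))
  x <- seq(lim[1], lim[2], by = h); y <- seq(lim2[1], lim2[2], by = h)
  any(inclusion_mask(a, x, y) & inclusion_mask(b, x, y))
}
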