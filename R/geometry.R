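#' Cumulative contour distance along an ordered path
#'
#' Arc length from the first point of an ordered planar path to every point
#' on it, computed as the running sum of Euclidean segment lengths. This is
#' the contour distance `c` used throughout the package: positions along the
#' dorsal or ventral perimeter of an embryo are measured as the route along
#' the perimeter from the anterior pole, not as the straight-line projection
#' onto the anterior-posterior (A-P) axis.
#'
#' @param points numeric matrix with two columns (x, y) in micrometres,
#'   ordered from the path start (typically the anterior pole).
#' @return numeric vector, same length as `nrow(points)`; first element 0,
#'   non-decreasing.
#' @examples
#' cumulative_contour_distance(rbind(c(0, 0), c(3, 4)))  # 0, 5
#' @export
cumulative_contour_distance <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) == 0L) stop("empty path")
  if (!all(is.finite(points))) stop("non-finite coordinates in path")
  if (nrow(points) == 1L) return(0)
  seg <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  c(0, cumsum(seg))
}

#' Projected distance of points onto the A-P axis
#'
#' Scalar projection of planar points onto the unit vector from the anterior
#' to the posterior pole. The anterior pole maps to 0 and the posterior pole
#' to the projected axis length L.
#'
#' @param points numeric matrix (n x 2) or length-2 vector, micrometres.
#' @param anterior_pole,posterior_pole length-2 numeric vectors, micrometres.
#' @return numeric vector of projected distances x in micrometres.
#' @export
project_to_axis <- function(points, anterior_pole, posterior_pole) {
  points <- as_point_matrix(points)
  axis <- as.numeric(posterior_pole) - as.numeric(anterior_pole)
  len <- sqrt(sum(axis^2))
  if (!is.finite(len) || len <= 0) stop("anterior and posterior poles coincide")
  u <- axis / len
  (points[, 1] - anterior_pole[1]) * u[1] + (points[, 2] - anterior_pole[2]) * u[2]
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L) stop("points must be an n x 2 matrix")
    points <- matrix(points, ncol = 2L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  points
}

#' Semi-ellipsoid embryo shape parameters
#'
#' The idealized asymmetric embryo is two semi-ellipsoids joined on the
#' coronal plane: the dorsal and ventral halves share the A-P semi-axis
#' (length/2) and the lateral semi-axis (lateral_diameter/2) but have
#' different midsagittal heights, which gives the two sides of the
#' midsagittal outline different curvatures and hence different perimeter
#' (contour) lengths.
#'
#' @param length embryo length along the A-P axis, micrometres.
#' @param lateral_diameter left-right diameter, micrometres.
#' @param dorsal_height,ventral_height midsagittal semi-axes of the dorsal
#'   and ventral halves, micrometres.
#' @return object of class `shape_params`.
#' @export
shape_params <- function(length = 560, lateral_diameter = 220,
                         dorsal_height = 92, ventral_height = 128) {
  vals <- c(length = length, lateral_diameter = lateral_diameter,
            dorsal_height = dorsal_height, ventral_height = ventral_height)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all shape parameters must be positive and finite")
  }
  structure(as.list(vals), class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf(
    "semi-ellipsoid embryo: length %.1f um, lateral diameter %.1f um, D/V heights %.1f/%.1f um\n",
    x$length, x$lateral_diameter, x$dorsal_height, x$ventral_height))
  invisible(x)
}

#' Midsagittal embryo contour
#'
#' Holds the ordered dorsal and ventral perimeter arcs of one embryo on the
#' midsagittal plane, pole-aligned so the anterior pole is at the origin and
#' the A-P axis is +x (dorsal arc y >= 0, ventral arc y <= 0). Both arcs run
#' from the anterior to the posterior pole. The object also caches, per arc,
#' the cumulative contour distance and the projected distance of every arc
#' point, which back the `c(x)` interpolation used by the distance
#' comparisons.
#'
#' @param dorsal_arc,ventral_arc n x 2 matrices (x, y) in micrometres,
#'   ordered anterior to posterior.
#' @param align if `TRUE` (default) the contour is rigidly rotated/translated
#'   into the canonical pole frame; poles are taken as the two contour points
#'   at maximal mutual distance.
#' @return object of class `midsagittal_contour` with elements `dorsal_arc`,
#'   `ventral_arc`, `anterior_pole`, `posterior_pole`, `L` (projected axis
#'   length), `C_D`, `C_V` (total contour lengths) and per-arc lookup tables.
#' @export
midsagittal_contour <- function(dorsal_arc, ventral_arc, align = TRUE) {
  dorsal_arc <- as_point_matrix(dorsal_arc)
  ventral_arc <- as_point_matrix(ventral_arc)
  if (nrow(dorsal_arc) < 2L || nrow(ventral_arc) < 2L) {
    stop("each arc needs at least two points")
  }
  if (align) {
    aligned <- align_arcs(dorsal_arc, ventral_arc)
    dorsal_arc <- aligned$dorsal
    ventral_arc <- aligned$ventral
  }
  anterior <- c(0, 0)
  L <- max(dorsal_arc[nrow(dorsal_arc), 1], ventral_arc[nrow(ventral_arc), 1])
  posterior <- c(L, 0)
  cd <- cumulative_contour_distance(dorsal_arc)
  cv <- cumulative_contour_distance(ventral_arc)
  obj <- list(
    dorsal_arc = dorsal_arc, ventral_arc = ventral_arc,
    anterior_pole = anterior, posterior_pole = posterior, L = L,
    C_D = cd[length(cd)], C_V = cv[length(cv)],
    c_dorsal = cd, c_ventral = cv,
    x_dorsal = dorsal_arc[, 1], x_ventral = ventral_arc[, 1]
  )
  class(obj) <- "midsagittal_contour"
  obj
}

#' @export
print.midsagittal_contour <- function(x, ...) {
  cat(sprintf(
    "midsagittal contour: L = %.1f um, C_D = %.1f um, C_V = %.1f um (%d/%d arc points)\n",
    x$L, x$C_D, x$C_V, nrow(x$dorsal_arc), nrow(x$ventral_arc)))
  invisible(x)
}

# Rigid alignment into the canonical frame: poles = the two contour points at
# maximal mutual distance (searched on the convex hull), anterior = the pole
# nearer the arcs' shared start, A-P axis rotated onto +x, dorsal side on top.
align_arcs <- function(dorsal_arc, ventral_arc) {
  pts <- rbind(dorsal_arc, ventral_arc)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hp))^2
  idx <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  p1 <- hp[idx[1], ]
  p2 <- hp[idx[2], ]
  start <- (dorsal_arc[1, ] + ventral_arc[1, ]) / 2
  if (sum((p1 - start)^2) <= sum((p2 - start)^2)) {
    anterior <- p1; posterior <- p2
  } else {
    anterior <- p2; posterior <- p1
  }
  u <- posterior - anterior
  u <- u / sqrt(sum(u^2))
  rot <- rbind(c(u[1], u[2]), c(-u[2], u[1]))  # rotates u onto +x
  xf <- function(m) t(rot %*% (t(m) - anterior))
  dorsal <- xf(dorsal_arc)
  ventral <- xf(ventral_arc)
  # dorsal side on top: flip y if the dorsal arc sits below the axis
  if (mean(dorsal[, 2]) < 0) {
    dorsal[, 2] <- -dorsal[, 2]
    ventral[, 2] <- -ventral[, 2]
  }
  list(dorsal = dorsal, ventral = ventral)
}

#' Build the semi-ellipsoid embryo
#'
#' Constructs the midsagittal contour (two half-ellipses with semi-axes
#' length/2 and the respective D/V height) together with a 3-D interior
#' predicate for the joined semi-ellipsoid body, used by the
#' reaction-diffusion simulator. The predicate tests
#' ((x-a)/a)^2 + (y/b_side)^2 + (z/(lateral_diameter/2))^2 <= 1 with
#' a = length/2 and b_side the dorsal height for y >= 0, ventral otherwise.
#'
#' @param params a [shape_params()] object.
#' @param n_points number of sample points per arc (>= 16).
#' @return list with elements `contour` (a [midsagittal_contour()]),
#'   `interior` (vectorized predicate `function(x, y, z)`), and `params`.
#' @export
build_semi_ellipsoid_shape <- function(params, n_points = 2001L) {
  stopifnot(inherits(params, "shape_params"))
  if (n_points < 16L) stop("n_points must be >= 16")
  a <- params$length / 2
  c_lat <- params$lateral_diameter / 2
  bd <- params$dorsal_height
  bv <- params$ventral_height
  t <- seq(0, pi, length.out = n_points)
  x <- a * (1 - cos(t))
  dorsal <- cbind(x, bd * sin(t))
  ventral <- cbind(x, -bv * sin(t))
  contour <- midsagittal_contour(dorsal, ventral, align = FALSE)
  interior <- function(x, y, z) {
    b <- ifelse(y >= 0, bd, bv)
    ((x - a) / a)^2 + (y / b)^2 + (z / c_lat)^2 <= 1
  }
  list(contour = contour, interior = interior, params = params)
}

#' Contour distance at given projected positions
#'
#' Piecewise-linear interpolation of cumulative arc length against projected
#' distance along one arc, i.e. the map `c(x)` for one side of the embryo.
#'
#' @param contour a [midsagittal_contour()].
#' @param x projected distances from the anterior pole, micrometres.
#' @param side `"D"` or `"V"`.
#' @return contour distances c in micrometres at each `x`.
#' @export
contour_distance_at <- function(contour, x, side = c("D", "V")) {
  side <- match.arg(side)
  if (side == "D") {
    stats::approx(contour$x_dorsal, contour$c_dorsal, xout = x, rule = 2)$y
  } else {
    stats::approx(contour$x_ventral, contour$c_ventral, xout = x, rule = 2)$y
  }
}

#' Dorsoventral contour-distance difference profile
#'
#' The relative shape-difference profile Delta c_embryo(x/L) / C_D with
#' Delta c_embryo = c_D(x) - c_V(x): at each fractional A-P position the
#' dorsal and ventral contour distances from the anterior pole are compared.
#' On a typical embryo the ventral perimeter is longer, so the difference is
#' negative over most of the axis.
#'
#' @param contour a [midsagittal_contour()].
#' @param xl_grid fractional positions x/L in [0, 1].
#' @return data.frame with columns `x_over_L`, `delta_c` (micrometres) and
#'   `delta_c_rel` (= delta_c / C_D, dimensionless).
#' @export
delta_c_embryo_profile <- function(contour, xl_grid = seq(0, 1, by = 0.01)) {
  if (any(xl_grid < 0 | xl_grid > 1)) stop("x/L grid must lie in [0, 1]")
  x <- xl_grid * contour$L
  cd <- contour_distance_at(contour, x, "D")
  cv <- contour_distance_at(contour, x, "V")
  delta <- cd - cv
  data.frame(x_over_L = xl_grid, delta_c = delta, delta_c_rel = delta / contour$C_D)
}

#' Average embryo frame
#'
#' Mean normalized midsagittal shape of a cohort: for each contour the dorsal
#' and ventral y positions (divided by that embryo's L) are interpolated on a
#' shared x/L grid, then averaged pointwise across embryos, sides kept
#' separate. This is the frame on which iso-concentration contour lines and
#' target boundary positions are drawn.
#'
#' @param cohort list of [midsagittal_contour()] objects (pole-aligned).
#' @param xl_grid shared fractional A-P grid.
#' @return object of class `average_frame`: data.frame with columns
#'   `x_over_L`, `yD_over_L`, `yV_over_L` plus attribute `n` (cohort size).
#' @export
average_embryo_frame <- function(cohort, xl_grid = seq(0, 1, by = 0.005)) {
  if (length(cohort) == 0L) stop("empty cohort")
  yd <- vapply(cohort, function(ct) {
    stats::approx(ct$dorsal_arc[, 1] / ct$L, ct$dorsal_arc[, 2] / ct$L,
                  xout = xl_grid, rule = 2)$y
  }, numeric(length(xl_grid)))
  yv <- vapply(cohort, function(ct) {
    stats::approx(ct$ventral_arc[, 1] / ct$L, ct$ventral_arc[, 2] / ct$L,
                  xout = xl_grid, rule = 2)$y
  }, numeric(length(xl_grid)))
  out <- data.frame(
    x_over_L = xl_grid,
    yD_over_L = rowMeans(yd),
    yV_over_L = rowMeans(yv)
  )
  attr(out, "n") <- length(cohort)
  class(out) <- c("average_frame", "data.frame")
  out
}
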