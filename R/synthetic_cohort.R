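#' Specification of a synthetic embryo cohort
#'
#' Bundles every parameter of the synthetic-data generator. Defaults describe
#' a wild-type-like cohort: 28 embryos, semi-ellipsoid shapes around the
#' 560/220/92/128 um asymmetric reference geometry, exponential Bcd gradients
#' in contour distance with length constants 104.8 um (dorsal) and 115.5 um
#' (ventral), additive imaging background 2.19/2.13 intensity units, and an
#' Hb readout generated from the background-free Bcd level through a Hill
#' switch with K_d = 5 intensity units and Hill coefficient n = 5.
#'
#' The default gradient amplitudes `b0_D`/`b0_V` are chosen so that the
#' noiseless background-free Bcd level crosses K_d at contour distances
#' 284.6 um (dorsal) and 279.1 um (ventral), i.e. the generator's true Hb
#' boundary positions sit at the reference wild-type locations; this fixes
#' b0_D ~ 75.7 and b0_V ~ 56.0 and reproduces the dorsal > ventral amplitude
#' ordering.
#'
#' Noise structure: `amplitude_cv` is a per-embryo multiplicative
#' perturbation of both sides' amplitudes (embryo-to-embryo reproducibility),
#' `window_cv_D`/`window_cv_V` are independent multiplicative perturbations
#' of every scanning-window Bcd value (ventral may be set larger), and
#' `hb_noise_sd` is additive Gaussian noise on the normalized Hb readout.
#'
#' @param n_embryos cohort size.
#' @param shape_mean [shape_params()] around which shapes are sampled.
#' @param shape_sd named numeric vector of per-field SDs in micrometres
#'   (`length`, `lateral_diameter`, `dorsal_height`, `ventral_height`).
#' @param lambda_c_D,lambda_c_V contour-distance length constants, um.
#' @param b0_D,b0_V gradient amplitudes at c = 0, intensity units
#'   (background-free).
#' @param amplitude_cv embryo-level amplitude coefficient of variation.
#' @param window_cv_D,window_cv_V per-window multiplicative noise CV.
#' @param background_mean_D,background_mean_V additive background, intensity
#'   units.
#' @param hill_Kd,hill_n Hill switch parameters of the Hb readout.
#' @param hb_noise_sd additive SD on normalized Hb.
#' @param pixel_scale micrometres per pixel for rasterization.
#' @param window_spacing A-P spacing between scanning-window centres, um;
#'   defaults to one pixel.
#' @param inset distance of window centres from the perimeter, um.
#' @param n_arc_points arc sampling density per side.
#' @param seed integer seed making a cohort fully reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_embryos = 28,
                        shape_mean = shape_params(560, 220, 92, 128),
                        shape_sd = c(length = 15, lateral_diameter = 8,
                                     dorsal_height = 6, ventral_height = 6),
                        lambda_c_D = 104.8, lambda_c_V = 115.5,
                        b0_D = 5 * exp(284.6 / 104.8),
                        b0_V = 5 * exp(279.1 / 115.5),
                        amplitude_cv = 0.15,
                        window_cv_D = 0.20, window_cv_V = 0.30,
                        background_mean_D = 2.19, background_mean_V = 2.13,
                        hill_Kd = 5, hill_n = 5,
                        hb_noise_sd = 0.10,
                        pixel_scale = 0.5,
                        window_spacing = pixel_scale,
                        inset = 6,
                        n_arc_points = 1201L,
                        seed = 1L) {
  if (n_embryos < 1) stop("n_embryos must be >= 1")
  if (lambda_c_D <= 0 || lambda_c_V <= 0) stop("length constants must be positive")
  if (b0_D <= 0 || b0_V <= 0) stop("amplitudes must be positive")
  cvs <- c(amplitude_cv, window_cv_D, window_cv_V, hb_noise_sd)
  if (any(cvs < 0)) stop("noise SDs/CVs must be >= 0")
  if (any(shape_sd < 0)) stop("shape SDs must be >= 0")
  spec <- list(
    n_embryos = as.integer(n_embryos), shape_mean = shape_mean,
    shape_sd = shape_sd,
    lambda_c_D = lambda_c_D, lambda_c_V = lambda_c_V,
    b0_D = b0_D, b0_V = b0_V, amplitude_cv = amplitude_cv,
    window_cv_D = window_cv_D, window_cv_V = window_cv_V,
    background_mean_D = background_mean_D,
    background_mean_V = background_mean_V,
    hill_Kd = hill_Kd, hill_n = hill_n, hb_noise_sd = hb_noise_sd,
    pixel_scale = pixel_scale, window_spacing = window_spacing,
    inset = inset, n_arc_points = as.integer(n_arc_points),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

# Inward offset of a perimeter arc: each point moved `inset` along the unit
# normal pointing toward the embryo midpoint (valid for convex outlines).
inset_arc <- function(arc, inset, L) {
  n <- nrow(arc)
  tx <- c(arc[2, 1] - arc[1, 1], arc[3:n, 1] - arc[1:(n - 2), 1],
          arc[n, 1] - arc[n - 1, 1])
  ty <- c(arc[2, 2] - arc[1, 2], arc[3:n, 2] - arc[1:(n - 2), 2],
          arc[n, 2] - arc[n - 1, 2])
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl
  ny <- tx / tl
  # flip normals that point away from the mid-axis point (L/2, 0)
  flip <- (nx * (L / 2 - arc[, 1]) + ny * (0 - arc[, 2])) < 0
  nx[flip] <- -nx[flip]
  ny[flip] <- -ny[flip]
  cbind(arc[, 1] + inset * nx, arc[, 2] + inset * ny)
}

# Scanning-window centre path for one side: the perimeter arc offset inward
# by `inset`, resampled at uniform projected-x steps of `spacing`.
window_centres <- function(arc, inset, spacing, L) {
  path <- inset_arc(arc, inset, L)
  ord <- order(path[, 1])
  path <- path[ord, , drop = FALSE]
  keep <- c(TRUE, diff(path[, 1]) > 1e-9)
  path <- path[keep, , drop = FALSE]
  xr <- range(path[, 1])
  xs <- seq(xr[1], xr[2], by = spacing)
  ys <- stats::approx(path[, 1], path[, 2], xout = xs)$y
  centres <- cbind(xs, ys)
  cc <- cumulative_contour_distance(centres)
  list(centres = centres, c = cc)
}

#' Hill input-output function
#'
#' `H = (B/Kd)^n / (1 + (B/Kd)^n)`: the fraction of maximal target
#' expression driven by a background-free morphogen level `B`. Evaluates to
#' 1/2 exactly at `B = Kd` for any Hill coefficient `n`.
#'
#' @param B morphogen level(s), background-free intensity units.
#' @param Kd half-maximal input level, same units as `B`.
#' @param n Hill coefficient (steepness of the on/off switch).
#' @return expression level(s) in [0, 1).
#' @export
hill_function <- function(B, Kd, n) {
  r <- (pmax(B, 0) / Kd)^n
  r / (1 + r)
}

#' Generate a synthetic embryo cohort
#'
#' Draws per-embryo shapes from truncated normals around the mean shape
#' (shapes with any height <= 20 um are rejected and redrawn), lays scanning
#' windows along each side's nuclear layer (perimeter offset inward by
#' `inset`, one window per `window_spacing` of projected distance), and fills
#' in raw Bcd and Hb channel values:
#' \itemize{
#'   \item Bcd: `B_raw(c) = B0_e exp(-c/lambda_c) (1 + eps) + background`,
#'     with `B0_e = b0 (1 + eta)` shared across sides of one embryo
#'     (`eta ~ N(0, amplitude_cv)`) and `eps ~ N(0, window_cv)` independent
#'     per window. `c` is the arc length along the window-centre path.
#'   \item Hb: Hill switch applied to the background-free noiseless Bcd
#'     level, plus `N(0, hb_noise_sd)` additive noise, clipped at 0.
#' }
#' Every embryo records its ground truth (amplitude, length constants, Hill
#' parameters, backgrounds and noiseless boundary positions), so downstream
#' estimates can be compared against known values.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`; each element has `contour`,
#'   `ground_truth` and `traces` (data.frame with columns `embryo`, `side`,
#'   `window_index`, `x_um`, `y_um`, `c_um`, `bcd_raw`, `hb_raw`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_embryos), function(i) generate_embryo(spec, i))
}

generate_embryo <- function(spec, embryo_id) {
  sm <- spec$shape_mean
  sd <- spec$shape_sd
  repeat {
    p <- c(
      length = stats::rnorm(1, sm$length, sd[["length"]]),
      lateral_diameter = stats::rnorm(1, sm$lateral_diameter, sd[["lateral_diameter"]]),
      dorsal_height = stats::rnorm(1, sm$dorsal_height, sd[["dorsal_height"]]),
      ventral_height = stats::rnorm(1, sm$ventral_height, sd[["ventral_height"]])
    )
    if (all(p > 0) && p[["dorsal_height"]] > 20 && p[["ventral_height"]] > 20) break
  }
  shape <- build_semi_ellipsoid_shape(
    shape_params(p[["length"]], p[["lateral_diameter"]],
                 p[["dorsal_height"]], p[["ventral_height"]]),
    n_points = spec$n_arc_points)
  contour <- shape$contour

  eta <- stats::rnorm(1, 0, spec$amplitude_cv)
  sides <- list(
    D = list(b0 = spec$b0_D * (1 + eta), lambda = spec$lambda_c_D,
             wcv = spec$window_cv_D, bg = spec$background_mean_D,
             arc = contour$dorsal_arc),
    V = list(b0 = spec$b0_V * (1 + eta), lambda = spec$lambda_c_V,
             wcv = spec$window_cv_V, bg = spec$background_mean_V,
             arc = contour$ventral_arc)
  )

  traces <- list()
  truth <- list()
  for (sn in names(sides)) {
    s <- sides[[sn]]
    w <- window_centres(s$arc, spec$inset, spec$window_spacing, contour$L)
    b_true <- s$b0 * exp(-w$c / s$lambda)
    eps <- stats::rnorm(length(b_true), 0, s$wcv)
    bcd_raw <- b_true * (1 + eps) + s$bg
    h_true <- hill_function(b_true, spec$hill_Kd, spec$hill_n)
    hb_raw <- pmax(h_true + stats::rnorm(length(h_true), 0, spec$hb_noise_sd), 0)
    traces[[sn]] <- data.frame(
      embryo = embryo_id, side = sn,
      window_index = seq_along(w$c),
      x_um = w$centres[, 1], y_um = w$centres[, 2], c_um = w$c,
      bcd_raw = bcd_raw, hb_raw = hb_raw
    )
    c_hb <- s$lambda * log(s$b0 / spec$hill_Kd)
    x_hb <- stats::approx(w$c, w$centres[, 1], xout = c_hb, rule = 2)$y
    truth[[sn]] <- list(b0 = s$b0, lambda = s$lambda, Kd = spec$hill_Kd,
                        n = spec$hill_n, background = s$bg,
                        c_hb = c_hb, x_hb = x_hb)
  }

  list(contour = contour, ground_truth = truth,
       traces = rbind(traces$D, traces$V))
}

#' Pool the traces of a cohort into one data.frame
#'
#' @param cohort a list returned by [generate_cohort()].
#' @return data.frame of all embryos' traces.
#' @export
cohort_traces <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "traces"))
}

#' Rasterize a synthetic embryo into channel images
#'
#' Paints a midsagittal image per channel: a cortical band of depth
#' `band_depth` under the perimeter carries the trace intensity at the
#' corresponding arc position, the interior carries the Bcd background (0
#' for Hb), and pixels outside the embryo are 0. The band is painted along
#' the band-centre path (perimeter offset inward by `band_depth`/2) so a
#' scanning window centred inside the band recovers the trace value.
#'
#' @param embryo one element of a [generate_cohort()] result.
#' @param pixel_scale micrometres per pixel.
#' @param band_depth cortical band depth, um.
#' @param quantize_8bit if TRUE, intensities are scaled to and stored on an
#'   8-bit integer range per channel.
#' @param max_canvas_px refuse images larger than this in either dimension.
#' @return list with matrices `bcd`, `hb` (rows = y, columns = x), the
#'   `origin_um` of pixel (1,1) and `pixel_scale`.
#' @export
rasterize_embryo <- function(embryo, pixel_scale = 0.5, band_depth = 10,
                             quantize_8bit = FALSE, max_canvas_px = 4096L) {
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  ct <- embryo$contour
  pad <- 5
  x0 <- -pad
  y0 <- min(ct$ventral_arc[, 2]) - pad
  nx <- ceiling((ct$L + 2 * pad) / pixel_scale)
  ny <- ceiling((max(ct$dorsal_arc[, 2]) - min(ct$ventral_arc[, 2]) + 2 * pad) / pixel_scale)
  if (nx > max_canvas_px || ny > max_canvas_px) {
    stop(sprintf("embryo needs a %d x %d px canvas, larger than allowed (%d)",
                 nx, ny, max_canvas_px))
  }
  px_x <- x0 + (seq_len(nx) - 0.5) * pixel_scale
  px_y <- y0 + (seq_len(ny) - 0.5) * pixel_scale

  bcd <- matrix(0, nrow = ny, ncol = nx)
  hb <- matrix(0, nrow = ny, ncol = nx)

  # interior mask from the two half-ellipse implicit equations
  a <- ct$L / 2
  bd <- max(ct$dorsal_arc[, 2])
  bv <- -min(ct$ventral_arc[, 2])
  X <- matrix(px_x, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(px_y, nrow = ny, ncol = nx)
  b_side <- ifelse(Y >= 0, bd, bv)
  inside <- ((X - a) / a)^2 + (Y / b_side)^2 <= 1
  bg_D <- embryo$ground_truth$D$background
  bg_V <- embryo$ground_truth$V$background
  bcd[inside] <- ifelse(Y[inside] >= 0, bg_D, bg_V)

  # paint the cortical band as discs along the band-centre path
  disc_r_px <- band_depth / 2 / pixel_scale
  dr <- ceiling(disc_r_px)
  offs <- expand.grid(dy = -dr:dr, dx = -dr:dr)
  offs <- offs[offs$dx^2 + offs$dy^2 <= disc_r_px^2, ]
  for (sn in c("D", "V")) {
    tr <- embryo$traces[embryo$traces$side == sn, ]
    arc <- if (sn == "D") ct$dorsal_arc else ct$ventral_arc
    path <- inset_arc(arc, band_depth / 2, ct$L)
    step <- max(1L, floor(pixel_scale / 2 /
                            max(stats::median(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)), 1e-6)))
    idx <- seq(1L, nrow(path), by = step)
    path <- path[idx, , drop = FALSE]
    # band intensity varies along the layer: each painted pixel carries the
    # trace value at its own projected position, so band parameterization and
    # window-centre path stay in register
    col_bcd <- stats::approx(tr$x_um, tr$bcd_raw, xout = px_x, rule = 2)$y
    col_hb <- stats::approx(tr$x_um, tr$hb_raw, xout = px_x, rule = 2)$y
    ci <- round((path[, 1] - x0) / pixel_scale + 0.5)
    ri <- round((path[, 2] - y0) / pixel_scale + 0.5)
    for (k in seq_len(nrow(path))) {
      rr <- ri[k] + offs$dy
      cc <- ci[k] + offs$dx
      ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
      ii <- cbind(rr[ok], cc[ok])
      keep <- inside[ii]
      ii <- ii[keep, , drop = FALSE]
      bcd[ii] <- col_bcd[ii[, 2]]
      hb[ii] <- col_hb[ii[, 2]]
    }
  }

  if (quantize_8bit) {
    q <- function(m) {
      top <- max(m)
      if (top <= 0) top <- 1
      round(m / top * 255) / 255 * top
    }
    bcd <- q(bcd)
    hb <- q(hb)
  }
  list(bcd = bcd, hb = hb, origin_um = c(x0, y0), pixel_scale = pixel_scale)
}
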