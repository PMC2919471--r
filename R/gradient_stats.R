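#' Fit an exponential gradient
#'
#' Least-squares fit of `B = B0 exp(-pos/lambda)` by linear regression of
#' log-intensity on position. Non-positive intensities (possible after
#' background subtraction) are excluded and counted. The anterior-most part
#' of the embryo, where the gradient deviates from a single exponential, is
#' excluded by restricting the fit range.
#'
#' @param pos positions (projected x or contour c), micrometres.
#' @param value intensities (background-subtracted for raw Bcd data).
#' @param range optional `c(lo, hi)` position window for the fit, um.
#' @param axis label stored with the fit (`"projected"` or `"contour"`).
#' @param refine if TRUE, the log-space estimate seeds a nonlinear
#'   least-squares refinement on the intensity scale.
#' @return list of class `gradient_fit`: `B0`, `lambda` (um), `axis`,
#'   `range`, `resid_norm` (RMS of log residuals), `n_used`, `n_excluded`.
#' @export
fit_exponential <- function(pos, value, range = NULL, axis = "projected",
                            refine = FALSE) {
  keep <- is.finite(pos) & is.finite(value)
  if (!is.null(range)) keep <- keep & pos >= range[1] & pos <= range[2]
  pos_r <- pos[keep]
  val_r <- value[keep]
  usable <- val_r > 0
  n_excluded <- sum(!usable)
  pos_r <- pos_r[usable]
  val_r <- val_r[usable]
  if (length(pos_r) < 5L && length(pos_r) != 2L) {
    if (length(pos_r) < 2L) stop("fewer than 2 usable points for exponential fit")
    if (length(pos_r) < 5L) stop("fewer than 5 usable points for exponential fit")
  }
  fit <- stats::lm(log(val_r) ~ pos_r)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) stop("exponential fit did not yield a decaying profile")
  B0 <- exp(unname(stats::coef(fit)[1]))
  lambda <- -1 / slope
  if (refine) {
    df <- data.frame(p = pos_r, v = val_r)
    nl <- tryCatch(
      minpack.lm::nlsLM(v ~ b0 * exp(-p / lam), data = df,
                        start = list(b0 = B0, lam = lambda),
                        lower = c(b0 = 1e-12, lam = 1e-6)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      B0 <- unname(stats::coef(nl)["b0"])
      lambda <- unname(stats::coef(nl)["lam"])
    }
  }
  structure(list(
    B0 = B0,
    lambda = lambda,
    axis = axis,
    range = if (is.null(range)) range(pos_r) else range,
    resid_norm = sqrt(mean(stats::residuals(fit)^2)),
    n_used = length(pos_r), n_excluded = n_excluded
  ), class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("exponential fit (%s axis): B0 = %.3g, lambda = %.2f um (%d points)\n",
              x$axis, x$B0, x$lambda, x$n_used))
  invisible(x)
}

#' Half-maximal expression boundary
#'
#' Locates the anterior expression boundary of a normalized target profile:
#' the most anterior downward crossing of the half-maximal level, linearly
#' interpolated between the bracketing windows. Both the projected and the
#' contour coordinate of the boundary are reported from the same window
#' pair. A short running-mean smoother suppresses spurious crossings from
#' window-level noise.
#'
#' @param x,c_pos projected and contour positions of the windows, um.
#' @param h normalized expression values.
#' @param level boundary level (default 0.5).
#' @param smooth_span odd number of windows for the running mean (1 = none).
#' @return list of class `boundary_estimate` with `x_b`, `c_b`, `level`.
#' @export
find_half_max_boundary <- function(x, c_pos, h, level = 0.5, smooth_span = 11L) {
  ord <- order(x)
  x <- x[ord]; c_pos <- c_pos[ord]; h <- h[ord]
  hs <- h
  if (smooth_span > 1L && length(h) > smooth_span) {
    k <- rep(1 / smooth_span, smooth_span)
    f <- stats::filter(h, k, sides = 2)
    hs <- ifelse(is.na(f), h, as.numeric(f))
  }
  down <- which(hs[-length(hs)] >= level & hs[-1] < level)
  if (length(down) == 0L) stop("profile does not cross the boundary level")
  if (length(down) > 1L) {
    warning(sprintf("%d downward crossings; using the most anterior", length(down)))
  }
  i <- down[1]
  w <- (level - hs[i]) / (hs[i + 1] - hs[i])
  structure(list(
    x_b = x[i] + w * (x[i + 1] - x[i]),
    c_b = c_pos[i] + w * (c_pos[i + 1] - c_pos[i]),
    level = level
  ), class = "boundary_estimate")
}

#' Measure the effective dissociation constant at the target boundary
#'
#' The operational K_d of the morphogen-target switch: the
#' background-subtracted Bcd intensity, linearly interpolated at the
#' contour-distance position of the target's half-maximal boundary.
#'
#' @param c_pos contour positions of the Bcd windows, um.
#' @param B background-subtracted Bcd intensities.
#' @param c_hb boundary contour position, um.
#' @return interpolated K_d (intensity units).
#' @export
measure_kd <- function(c_pos, B, c_hb) {
  if (c_hb < min(c_pos) || c_hb > max(c_pos)) {
    stop("boundary position outside the trace support")
  }
  stats::approx(c_pos, B, xout = c_hb)$y
}

#' Fit the Hill input-output relation
#'
#' Nonlinear least-squares fit of `H = (B/Kd)^n / (1 + (B/Kd)^n)` to paired
#' (background-subtracted Bcd, normalized target) observations. The Hill
#' coefficient `n` is always free; `Kd` is either co-fitted or fixed at a
#' measured value. A multi-start over n in {1, 3, 5, 8} guards against local
#' minima. Pairs with B <= 0 are excluded.
#'
#' @param B background-subtracted morphogen intensities.
#' @param H normalized target expression values.
#' @param Kd_mode `"fitted"` (co-fit Kd) or `"fixed"` (use `Kd`).
#' @param Kd fixed Kd when `Kd_mode = "fixed"`; also the Kd start otherwise.
#' @param n_starts Hill-coefficient starting values.
#' @return list of class `hill_fit`: `Kd`, `n`, `Kd_mode`, `rss`, `n_pairs`.
#' @export
fit_hill <- function(B, H, Kd_mode = c("fitted", "fixed"), Kd = NULL,
                     n_starts = c(1, 3, 5, 8)) {
  Kd_mode <- match.arg(Kd_mode)
  keep <- is.finite(B) & is.finite(H) & B > 0
  B <- B[keep]; H <- H[keep]
  if (length(B) < 8L) stop("need at least 8 usable (B, H) pairs")
  if (sum(H > 0.5) < 2L || sum(H < 0.5) < 2L) {
    stop("pairs do not span both sides of the half-maximal level")
  }
  if (Kd_mode == "fixed" && is.null(Kd)) stop("Kd must be supplied when fixed")
  if (is.null(Kd)) Kd <- stats::approx(stats::ecdf(B)(B), B, xout = 0.5)$y
  df <- data.frame(B = B, H = H)
  best <- NULL
  for (n0 in n_starts) {
    fit <- tryCatch({
      if (Kd_mode == "fixed") {
        minpack.lm::nlsLM(H ~ (B / Kd)^n / (1 + (B / Kd)^n), data = df,
                          start = list(n = n0), lower = c(n = 0.05),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(H ~ (B / K)^n / (1 + (B / K)^n), data = df,
                          start = list(K = Kd, n = n0),
                          lower = c(K = 1e-6, n = 0.05),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  structure(list(
    Kd = if (Kd_mode == "fixed") Kd else unname(cf["K"]),
    n = unname(cf["n"]),
    Kd_mode = Kd_mode, rss = best$rss, n_pairs = length(B)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Kd = %.3g (%s), n = %.2f (%d pairs)\n",
              x$Kd, x$Kd_mode, x$n, x$n_pairs))
  invisible(x)
}

#' Cross-embryo intensity noise profile
#'
#' The reproducibility of a gradient across a cohort: windows are binned on
#' the chosen axis, each embryo contributes its per-bin mean, and the noise
#' is the across-embryo standard deviation divided by the across-embryo mean
#' (deltaB/B). Bins with fewer contributing embryos than `min_embryos` are
#' omitted. Noise from measurement and background is not subtracted.
#'
#' @param traces pooled cohort traces (`embryo`, `side`, positions, value).
#' @param axis `"projected"` or `"contour"`.
#' @param interval bin width, um.
#' @param value value column.
#' @param min_embryos minimum embryos per reported bin.
#' @return data.frame with `side`, `bin_center`, `mean`, `sd`, `noise`
#'   (= sd/mean) and `n_embryos`.
#' @export
intensity_noise_profile <- function(traces, axis = c("projected", "contour"),
                                    interval = 5.5, value = "bcd_raw",
                                    min_embryos = 3L) {
  axis <- match.arg(axis)
  pos <- if (axis == "projected") traces$x_um else traces$c_um
  bin <- floor(pos / interval)
  key <- paste(traces$side, bin, traces$embryo, sep = "\r")
  em <- tapply(traces[[value]], key, mean)
  parts <- strsplit(names(em), "\r", fixed = TRUE)
  side <- vapply(parts, `[[`, "", 1L)
  b <- as.numeric(vapply(parts, `[[`, "", 2L))
  key2 <- paste(side, b, sep = "\r")
  m <- tapply(em, key2, mean)
  s <- tapply(em, key2, stats::sd)
  ne <- tapply(em, key2, length)
  parts2 <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(
    side = vapply(parts2, `[[`, "", 1L),
    bin_center = (as.numeric(vapply(parts2, `[[`, "", 2L)) + 0.5) * interval,
    mean = as.numeric(m), sd = as.numeric(s),
    n_embryos = as.integer(ne)
  )
  out$noise <- out$sd / out$mean
  out <- out[out$n_embryos >= min_embryos, ]
  out <- out[order(out$side, out$bin_center), ]
  rownames(out) <- NULL
  out
}

#' Convert intensity noise to positional error
#'
#' Propagates intensity variability into distance: `sigma_c = deltaB /
#' |dB/dc|`, with the local gradient slope estimated by linear regression of
#' the mean profile over a centred span of bins. For an exponential gradient
#' this reduces to `lambda * (deltaB/B)`. Bins where the local slope is
#' (numerically) zero report `NA`.
#'
#' @param profile one side of an [intensity_noise_profile()] result
#'   (columns `bin_center`, `mean`, `sd`).
#' @param span odd number of bins for the local slope regression.
#' @return `profile` with columns `slope` and `sigma_c` (um) appended.
#' @export
positional_error <- function(profile, span = 5L) {
  n <- nrow(profile)
  half <- span %/% 2L
  slope <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    if (length(j) >= 2L) {
      slope[i] <- stats::cov(profile$bin_center[j], profile$mean[j]) /
        stats::var(profile$bin_center[j])
    }
  }
  profile$slope <- slope
  eps <- max(abs(profile$mean), na.rm = TRUE) * 1e-12
  profile$sigma_c <- ifelse(abs(slope) > eps, profile$sd / abs(slope), NA_real_)
  profile
}

#' Bootstrap standard deviation of a cohort statistic
#'
#' Resamples embryos with replacement, recomputes a cohort-level statistic
#' on each replicate and returns the standard deviation across replicates.
#' Replicates on which the statistic fails are dropped (an error is raised
#' if more than 10 percent fail).
#'
#' @param statistic function taking a list of embryos and returning a
#'   numeric scalar.
#' @param cohort list of embryos (any per-embryo objects).
#' @param n_reps number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return list with `sd`, `n_ok`, `n_failed`.
#' @export
bootstrap_sd <- function(statistic, cohort, n_reps = 1000L, seed = 1L) {
  if (length(cohort) < 3L) stop("cohort size must be >= 3")
  if (n_reps < 100L) stop("n_reps must be >= 100")
  set.seed(seed)
  vals <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(length(cohort), replace = TRUE)
    vals[r] <- tryCatch(statistic(cohort[idx]), error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.1 * n_reps) {
    stop(sprintf("statistic failed on %d of %d bootstrap replicates", n_failed, n_reps))
  }
  list(sd = stats::sd(vals, na.rm = TRUE), n_ok = n_reps - n_failed,
       n_failed = n_failed)
}

#' Two-sample comparison of dorsal and ventral values
#'
#' Classical two-tailed Student's t-test (pooled variance by default; Welch
#' by flag) of per-embryo dorsal versus ventral values. Degenerate input
#' with zero variance on both sides and equal means reports p = 1.
#'
#' @param dorsal,ventral numeric vectors (one value per embryo).
#' @param var_equal pooled-variance Student test if TRUE, Welch otherwise.
#' @return list with `t`, `p`, `df`, `mean_D`, `mean_V`.
#' @export
compare_sides_ttest <- function(dorsal, ventral, var_equal = TRUE) {
  if (length(dorsal) < 2L || length(ventral) < 2L) {
    stop("need at least two values per side")
  }
  if (stats::sd(dorsal) == 0 && stats::sd(ventral) == 0) {
    same <- isTRUE(all.equal(mean(dorsal), mean(ventral)))
    return(list(t = if (same) 0 else Inf, p = if (same) 1 else 0,
                df = length(dorsal) + length(ventral) - 2,
                mean_D = mean(dorsal), mean_V = mean(ventral)))
  }
  tt <- stats::t.test(dorsal, ventral, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_D = mean(dorsal), mean_V = mean(ventral))
}

#' Per-bin dorsal-ventral t-tests around a position
#'
#' For a set of bins around a position of interest (e.g. the Hb boundary),
#' computes each embryo's mean intensity per bin and side and runs a
#' two-tailed Student's t-test between sides per bin.
#'
#' @param traces pooled cohort traces.
#' @param axis,interval,value as in [intensity_noise_profile()].
#' @param center position of the central bin, um.
#' @param n_bins number of bins tested (centred on `center`).
#' @param var_equal pooled-variance Student test if TRUE.
#' @param p_adjust `"none"` (raw per-bin p-values, the default) or
#'   `"bonferroni"` across the tested bins.
#' @return data.frame with `bin_center`, `t`, `p`, `mean_D`, `mean_V`, `n_D`,
#'   `n_V`.
#' @export
boundary_region_ttests <- function(traces, axis = c("projected", "contour"),
                                   interval = 5.5, value = "bcd_raw",
                                   center, n_bins = 5L, var_equal = TRUE,
                                   p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  axis <- match.arg(axis)
  pos <- if (axis == "projected") traces$x_um else traces$c_um
  center_bin <- floor(center / interval)
  half <- n_bins %/% 2L
  bins <- (center_bin - half):(center_bin + half)
  out <- lapply(bins, function(b) {
    sel <- floor(pos / interval) == b
    sub <- traces[sel, ]
    dm <- tapply(sub[[value]][sub$side == "D"], sub$embryo[sub$side == "D"], mean)
    vm <- tapply(sub[[value]][sub$side == "V"], sub$embryo[sub$side == "V"], mean)
    tt <- compare_sides_ttest(as.numeric(dm), as.numeric(vm), var_equal = var_equal)
    data.frame(bin_center = (b + 0.5) * interval, t = tt$t, p = tt$p,
               mean_D = tt$mean_D, mean_V = tt$mean_V,
               n_D = length(dm), n_V = length(vm))
  })
  out <- do.call(rbind, out)
  if (p_adjust == "bonferroni") {
    out$p <- stats::p.adjust(out$p, method = "bonferroni")
  }
  out
}

# Monotone decreasing section of a binned profile (posterior to the anterior
# peak), prepared for threshold -> position inverse interpolation.
monotone_section <- function(profile, max_pos = Inf) {
  pr <- profile[profile$bin_center <= max_pos, ]
  pr <- pr[order(pr$bin_center), ]
  start <- which.max(pr$mean)
  pr <- pr[start:nrow(pr), ]
  keep <- pr$mean <= cummin(pr$mean)
  pr[keep, ]
}

#' Iso-concentration contour lines on the average embryo frame
#'
#' For a series of intensity thresholds t_k, finds by interpolation the
#' dorsal and ventral positions where the mean gradient profile equals t_k,
#' in both distance systems, and reports the dorsoventral position
#' differences Delta x_Bcd = x_D - x_V and Delta c_Bcd = c_D - c_V. When an
#' average frame is supplied, the frame coordinates of each threshold
#' position are attached so the contour lines can be drawn on the mean
#' embryo shape. Thresholds outside the shared monotone range of both
#' profiles are skipped.
#'
#' @param profile_x,profile_c binned mean profiles (columns `side`,
#'   `bin_center`, `mean`) on the projected and contour axes.
#' @param thresholds intensity thresholds; if NULL, a regular series with
#'   step `interval` over the shared anterior-half range is used (use 0.5,
#'   1 and 1.5 for 1x-, 2x- and 3x-dosage cohorts).
#' @param interval threshold step when `thresholds` is NULL.
#' @param frame optional [average_embryo_frame()].
#' @param L mean embryo length, um (needed with `frame`).
#' @param anterior_half restrict to positions below this fraction of the
#'   profile support (the anterior part where the morphogen acts).
#' @return data.frame with `threshold`, `x_D`, `x_V`, `c_D`, `c_V`,
#'   `delta_x`, `delta_c` and, with a frame, `y_D`, `y_V` (um).
#' @export
iso_concentration_contours <- function(profile_x, profile_c, thresholds = NULL,
                                       interval = 1, frame = NULL, L = NULL,
                                       anterior_half = 0.55) {
  secs <- list(
    x_D = monotone_section(profile_x[profile_x$side == "D", ],
                           anterior_half * max(profile_x$bin_center)),
    x_V = monotone_section(profile_x[profile_x$side == "V", ],
                           anterior_half * max(profile_x$bin_center)),
    c_D = monotone_section(profile_c[profile_c$side == "D", ],
                           anterior_half * max(profile_c$bin_center)),
    c_V = monotone_section(profile_c[profile_c$side == "V", ],
                           anterior_half * max(profile_c$bin_center))
  )
  lo <- max(vapply(secs, function(s) min(s$mean), 0))
  hi <- min(vapply(secs, function(s) max(s$mean), 0))
  if (is.null(thresholds)) {
    thresholds <- seq(ceiling(lo / interval) * interval, hi, by = interval)
  }
  ok <- thresholds > lo & thresholds < hi
  if (!all(ok)) {
    message(sprintf("%d threshold(s) outside the shared profile range skipped",
                    sum(!ok)))
  }
  thresholds <- sort(thresholds[ok])
  if (length(thresholds) == 0L) stop("no usable thresholds")
  pos_at <- function(sec, t) stats::approx(sec$mean, sec$bin_center, xout = t)$y
  out <- data.frame(
    threshold = thresholds,
    x_D = pos_at(secs$x_D, thresholds), x_V = pos_at(secs$x_V, thresholds),
    c_D = pos_at(secs$c_D, thresholds), c_V = pos_at(secs$c_V, thresholds)
  )
  out$delta_x <- out$x_D - out$x_V
  out$delta_c <- out$c_D - out$c_V
  if (!is.null(frame)) {
    if (is.null(L)) stop("L is required to place thresholds on the frame")
    out$y_D <- stats::approx(frame$x_over_L, frame$yD_over_L,
                             xout = out$x_D / L, rule = 2)$y * L
    out$y_V <- stats::approx(frame$x_over_L, frame$yV_over_L,
                             xout = out$x_V / L, rule = 2)$y * L
  }
  out
}

#' Target boundary slant statistics
#'
#' Paired dorsal-ventral comparison of per-embryo target boundary positions
#' in both distance systems: cohort means of Delta x = x_D - x_V and
#' Delta c = c_D - c_V, their SDs, paired two-tailed t-tests, and the
#' per-side across-embryo SD of the contour boundary position (sigma c of
#' the boundary). Embryos lacking one side are excluded with a warning.
#'
#' @param boundaries data.frame with columns `embryo`, `side`, `x_b`, `c_b`.
#' @return list with `delta_x`, `delta_c` (each: mean, sd, p, n) and
#'   `sigma_c_hb` (named per-side SDs).
#' @export
target_slant <- function(boundaries) {
  d <- boundaries[boundaries$side == "D", ]
  v <- boundaries[boundaries$side == "V", ]
  common <- intersect(d$embryo, v$embryo)
  if (length(common) < nrow(d) || length(common) < nrow(v)) {
    warning("unpaired embryos excluded from the slant analysis")
  }
  d <- d[match(common, d$embryo), ]
  v <- v[match(common, v$embryo), ]
  dx <- d$x_b - v$x_b
  dc <- d$c_b - v$c_b
  paired_p <- function(z) {
    if (stats::sd(z) == 0) return(if (isTRUE(all.equal(mean(z), 0))) 1 else 0)
    stats::t.test(z)$p.value
  }
  px <- paired_p(dx)
  pc <- paired_p(dc)
  list(
    delta_x = list(mean = mean(dx), sd = stats::sd(dx), p = px, n = length(dx)),
    delta_c = list(mean = mean(dc), sd = stats::sd(dc), p = pc, n = length(dc)),
    sigma_c_hb = c(D = stats::sd(d$c_b), V = stats::sd(v$c_b)),
    x_b = c(D = mean(d$x_b), V = mean(v$x_b)),
    c_b = c(D = mean(d$c_b), V = mean(v$c_b))
  )
}
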