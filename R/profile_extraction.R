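#' Scan the cortical layer of a midsagittal image
#'
#' Slides a circular intensity window (default area 25 um^2, i.e. radius
#' ~2.82 um, smaller than one nucleus) along the nuclear layer of each side:
#' window centres follow the embryo perimeter offset inward by `inset`
#' (default 6 um), stepping one pixel at a time along the A-P projection.
#' At each position the mean in-window intensity of every channel is
#' recorded together with the centre coordinates, the projected distance x
#' and the contour distance c (cumulative arc length over the window
#' centres).
#'
#' @param image a raster as returned by [rasterize_embryo()]: a list of
#'   channel matrices (rows = y, columns = x) plus `origin_um` and
#'   `pixel_scale`.
#' @param contour the [midsagittal_contour()] of the imaged embryo, in the
#'   same coordinate frame.
#' @param window_area window area in um^2.
#' @param inset window-centre distance from the perimeter, um.
#' @param spacing A-P step between window centres, um; defaults to one pixel.
#' @param channels names of the channel matrices to average.
#' @return data.frame with columns `side`, `window_index`, `x_um`, `y_um`,
#'   `c_um` and one column per channel.
#' @export
scan_cortical_layer <- function(image, contour, window_area = 25, inset = 6,
                                spacing = image$pixel_scale,
                                channels = c("bcd", "hb")) {
  ps <- image$pixel_scale
  radius <- sqrt(window_area / pi)
  r_px <- radius / ps
  dr <- ceiling(r_px)
  offs <- expand.grid(dy = -dr:dr, dx = -dr:dr)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_px^2, ]
  dims <- dim(image[[channels[1]]])

  out <- lapply(c(D = "D", V = "V"), function(sn) {
    arc <- if (sn == "D") contour$dorsal_arc else contour$ventral_arc
    w <- window_centres(arc, inset, spacing, contour$L)
    ci <- round((w$centres[, 1] - image$origin_um[1]) / ps + 0.5)
    ri <- round((w$centres[, 2] - image$origin_um[2]) / ps + 0.5)
    vals <- matrix(NA_real_, nrow = nrow(w$centres), ncol = length(channels),
                   dimnames = list(NULL, channels))
    for (k in seq_len(nrow(w$centres))) {
      rr <- ri[k] + offs$dy
      cc <- ci[k] + offs$dx
      if (any(rr < 1 | rr > dims[1] | cc < 1 | cc > dims[2])) {
        stop(sprintf("scanning window %d on side %s extends outside the image", k, sn))
      }
      ii <- cbind(rr, cc)
      for (ch in channels) vals[k, ch] <- mean(image[[ch]][ii])
    }
    df <- data.frame(side = sn, window_index = seq_len(nrow(w$centres)),
                     x_um = w$centres[, 1], y_um = w$centres[, 2], c_um = w$c)
    cbind(df, as.data.frame(vals))
  })
  out <- rbind(out$D, out$V)
  rownames(out) <- NULL
  out
}

#' Subtract imaging background from a trace channel
#'
#' Removes a side-specific constant background (measured from Bcd-null
#' embryos under identical staining conditions) from a channel. Values are
#' allowed to go negative; no clipping is applied.
#'
#' @param trace data.frame with columns `side` and the channel column.
#' @param background named numeric, e.g. `c(D = 2.19, V = 2.13)`; a single
#'   unnamed value is applied to both sides.
#' @param channel channel column to correct.
#' @param out_channel name of the corrected column to add.
#' @return `trace` with the corrected column appended.
#' @export
subtract_background <- function(trace, background = c(D = 2.19, V = 2.13),
                                channel = "bcd_raw", out_channel = "bcd") {
  if (any(background < 0)) stop("background must be >= 0")
  if (is.null(names(background))) background <- c(D = background[[1]], V = background[[1]])
  trace[[out_channel]] <- trace[[channel]] - unname(background[trace$side])
  trace
}

#' Normalize target expression traces
#'
#' Per embryo, rescales a target channel (e.g. Hb) so that the mean over the
#' anterior expression plateau maps to 1 and the mean over the
#' non-expression trough maps to 0:
#' `H_norm = (H - mean_trough) / (mean_plateau - mean_trough)`.
#' Windows are selected by fractional A-P position x/L; L is taken from the
#' embryo's own window support (`max(x) + inset`) unless supplied.
#'
#' @param traces data.frame with columns `embryo`, `x_um` and the channel.
#' @param plateau_window,trough_window x/L ranges for the expression plateau
#'   and the non-expression region.
#' @param channel channel to normalize.
#' @param out_channel name of the normalized column.
#' @param inset window inset used when reconstructing L from the traces, um.
#' @param L optional named vector of embryo lengths, um.
#' @return `traces` with the normalized column appended.
#' @export
normalize_expression <- function(traces, plateau_window = c(0.10, 0.30),
                                 trough_window = c(0.65, 0.80),
                                 channel = "hb_raw", out_channel = "hb_norm",
                                 inset = 6, L = NULL) {
  traces[[out_channel]] <- NA_real_
  for (e in unique(traces$embryo)) {
    sel <- traces$embryo == e
    x <- traces$x_um[sel]
    Le <- if (is.null(L)) max(x) + inset else unname(L[[as.character(e)]])
    xl <- x / Le
    v <- traces[[channel]][sel]
    in_plateau <- xl >= plateau_window[1] & xl <= plateau_window[2]
    in_trough <- xl >= trough_window[1] & xl <= trough_window[2]
    if (!any(in_plateau) || !any(in_trough)) {
      stop(sprintf("embryo %s: empty plateau or trough window", e))
    }
    hi <- mean(v[in_plateau])
    lo <- mean(v[in_trough])
    if (hi <= lo) stop(sprintf("embryo %s: no expression contrast", e))
    traces[[out_channel]][sel] <- (v - lo) / (hi - lo)
  }
  traces
}

#' Bin pooled cohort traces on a distance axis
#'
#' Pools all scanning windows of a cohort and bins them into half-open
#' intervals `[k*interval, (k+1)*interval)` on the chosen axis (projected
#' distance x or contour distance c), reporting the per-bin mean, SD and
#' counts. Bins supported by fewer than `min_windows` windows are dropped.
#'
#' @param traces pooled trace data.frame (must have `side`, `embryo`, the
#'   axis column and the value column).
#' @param axis `"projected"` (bins on `x_um`) or `"contour"` (bins on
#'   `c_um`).
#' @param interval bin width, um (e.g. 11 pixels at 0.5 um/px = 5.5 um).
#' @param value value column to aggregate.
#' @param min_windows minimum windows per reported bin.
#' @return data.frame with `side`, `axis`, `bin_center`, `mean`, `sd`,
#'   `n_windows`, `n_embryos`, ordered by side and position.
#' @export
bin_profiles <- function(traces, axis = c("projected", "contour"),
                         interval = 5.5, value = "bcd_raw",
                         min_windows = 1L) {
  axis <- match.arg(axis)
  if (interval <= 0) stop("interval must be positive")
  pos <- if (axis == "projected") traces$x_um else traces$c_um
  if (nrow(traces) == 0L) {
    warning("no data to bin; returning empty profile")
    return(data.frame(side = character(), axis = character(),
                      bin_center = numeric(), mean = numeric(), sd = numeric(),
                      n_windows = integer(), n_embryos = integer()))
  }
  bin <- floor(pos / interval)
  key <- interaction(traces$side, bin, drop = TRUE)
  agg <- function(f) tapply(traces[[value]], key, f)
  m <- agg(mean)
  s <- agg(stats::sd)
  nw <- agg(length)
  ne <- tapply(traces$embryo, key, function(e) length(unique(e)))
  parts <- strsplit(names(m), ".", fixed = TRUE)
  side <- vapply(parts, `[[`, "", 1L)
  b <- as.numeric(vapply(parts, `[[`, "", 2L))
  out <- data.frame(side = side, axis = axis,
                    bin_center = (b + 0.5) * interval,
                    mean = as.numeric(m), sd = as.numeric(s),
                    n_windows = as.integer(nw), n_embryos = as.integer(ne))
  out <- out[out$n_windows >= min_windows, ]
  out <- out[order(out$side, out$bin_center), ]
  rownames(out) <- NULL
  out
}
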