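#' Full dorsal-ventral analysis of a cohort
#'
#' Runs the complete comparative analysis on a cohort of cortical traces:
#' background subtraction, Hb normalization, per-embryo exponential gradient
#' fits on both distance axes, half-maximal boundary detection, boundary
#' slant statistics, per-embryo K_d measurement and Hill fits, binned
#' cohort profiles, intensity-noise and positional-error profiles, and
#' iso-concentration contours.
#'
#' @param traces pooled cohort traces (columns `embryo`, `side`,
#'   `window_index`, `x_um`, `y_um`, `c_um`, `bcd_raw`, `hb_raw`).
#' @param contours optional list of [midsagittal_contour()] objects (one per
#'   embryo, in trace order) used for the average frame.
#' @param background per-side additive Bcd background.
#' @param bin_interval bin width for cohort profiles, um.
#' @param fit_window fractional window (of each profile's position support)
#'   for the exponential fits; the anterior-most part, where the gradient
#'   deviates from a single exponential, is excluded.
#' @param inset scanning-window inset, um.
#' @param iso_interval threshold step of the iso-concentration contours.
#' @param boundary_smooth running-mean span (windows) for boundary
#'   detection.
#' @param fit_hill_per_embryo fit the Hill relation per embryo-side (slower
#'   but gives per-embryo n estimates); if FALSE only cohort-level fits are
#'   returned.
#' @param hill_input input variable of the per-embryo Hill fits:
#'   `"smoothed"` (default) regresses expression on the embryo's own fitted
#'   exponential gradient evaluated at each window — a regression-calibration
#'   step that removes the attenuation of the Hill coefficient caused by
#'   window-level intensity noise in the input; `"windowed"` uses the raw
#'   background-subtracted window intensities.
#' @param noise_min_embryos minimum embryos per noise bin.
#' @return list with elements `traces`, `fits`, `fit_summary`, `boundaries`,
#'   `slant`, `kd`, `hill`, `io_summary`, `profiles_x`, `profiles_c`,
#'   `noise_x`, `noise_c`, `sigma_c`, `iso`, `frame`, `boundary_tests`.
#' @export
analyze_cohort <- function(traces, contours = NULL,
                           background = c(D = 2.19, V = 2.13),
                           bin_interval = 5.5, fit_window = c(0.10, 0.60),
                           inset = 6, iso_interval = 1,
                           boundary_smooth = 11L,
                           fit_hill_per_embryo = TRUE,
                           hill_input = c("smoothed", "windowed"),
                           noise_min_embryos = 3L) {
  hill_input <- match.arg(hill_input)
  tr <- subtract_background(traces, background)
  tr <- normalize_expression(tr, inset = inset)

  embryos <- unique(tr$embryo)
  fits <- list()
  boundaries <- list()
  kd <- list()
  hill <- list()
  for (e in embryos) {
    for (sn in c("D", "V")) {
      sub <- tr[tr$embryo == e & tr$side == sn, ]
      sub <- sub[order(sub$x_um), ]
      fx <- fit_exponential(sub$x_um, sub$bcd,
                            range = fit_window * max(sub$x_um), axis = "projected")
      fc <- fit_exponential(sub$c_um, sub$bcd,
                            range = fit_window * max(sub$c_um), axis = "contour")
      fits[[length(fits) + 1L]] <- data.frame(
        embryo = e, side = sn,
        axis = c("projected", "contour"),
        B0 = c(fx$B0, fc$B0), lambda = c(fx$lambda, fc$lambda),
        resid_norm = c(fx$resid_norm, fc$resid_norm))
      bd <- tryCatch(
        find_half_max_boundary(sub$x_um, sub$c_um, sub$hb_norm,
                               smooth_span = boundary_smooth),
        error = function(err) NULL)
      if (!is.null(bd)) {
        boundaries[[length(boundaries) + 1L]] <- data.frame(
          embryo = e, side = sn, x_b = bd$x_b, c_b = bd$c_b)
        kd_e <- measure_kd(sub$c_um, sub$bcd, bd$c_b)
        kd[[length(kd) + 1L]] <- data.frame(embryo = e, side = sn, Kd = kd_e)
        if (fit_hill_per_embryo && kd_e > 0) {
          b_in <- if (hill_input == "smoothed") {
            fc$B0 * exp(-sub$c_um / fc$lambda)
          } else {
            sub$bcd
          }
          hf <- tryCatch(
            fit_hill(b_in, sub$hb_norm, Kd_mode = "fitted", Kd = kd_e),
            error = function(err) NULL)
          if (!is.null(hf)) {
            hill[[length(hill) + 1L]] <- data.frame(
              embryo = e, side = sn, Kd = kd_e, n = hf$n,
              Kd_fit = hf$Kd)
          }
        }
      }
    }
  }
  fits <- do.call(rbind, fits)
  boundaries <- do.call(rbind, boundaries)
  kd <- do.call(rbind, kd)
  hill <- if (length(hill)) do.call(rbind, hill) else NULL

  fit_summary <- do.call(rbind, lapply(split(fits, list(fits$side, fits$axis)),
    function(g) data.frame(side = g$side[1], axis = g$axis[1],
                           lambda_mean = mean(g$lambda),
                           lambda_sd = stats::sd(g$lambda),
                           lambda_se = stats::sd(g$lambda) / sqrt(nrow(g)),
                           B0_mean = mean(g$B0))))
  rownames(fit_summary) <- NULL

  slant <- target_slant(boundaries)

  io_summary <- NULL
  if (!is.null(kd) && nrow(kd) > 0) {
    kd_t <- compare_sides_ttest(kd$Kd[kd$side == "D"], kd$Kd[kd$side == "V"])
    io_summary <- list(
      Kd = list(mean_D = kd_t$mean_D, mean_V = kd_t$mean_V,
                sd_D = stats::sd(kd$Kd[kd$side == "D"]),
                sd_V = stats::sd(kd$Kd[kd$side == "V"]), p = kd_t$p))
    if (!is.null(hill)) {
      n_t <- compare_sides_ttest(hill$n[hill$side == "D"], hill$n[hill$side == "V"])
      io_summary$n <- list(mean_D = n_t$mean_D, mean_V = n_t$mean_V,
                           sd_D = stats::sd(hill$n[hill$side == "D"]),
                           sd_V = stats::sd(hill$n[hill$side == "V"]), p = n_t$p)
    }
  }

  profiles_x <- bin_profiles(tr, "projected", bin_interval, value = "bcd_raw")
  profiles_c <- bin_profiles(tr, "contour", bin_interval, value = "bcd_raw")
  noise_x <- intensity_noise_profile(tr, "projected", bin_interval,
                                     value = "bcd_raw",
                                     min_embryos = noise_min_embryos)
  noise_c <- intensity_noise_profile(tr, "contour", bin_interval,
                                     value = "bcd_raw",
                                     min_embryos = noise_min_embryos)

  sigma_c <- c(D = NA_real_, V = NA_real_)
  for (sn in c("D", "V")) {
    prof <- positional_error(noise_c[noise_c$side == sn, ])
    ok <- is.finite(prof$sigma_c)
    if (any(ok)) {
      sigma_c[sn] <- stats::approx(prof$bin_center[ok], prof$sigma_c[ok],
                                   xout = slant$c_b[sn], rule = 2)$y
    }
  }

  frame <- if (!is.null(contours)) average_embryo_frame(contours) else NULL
  L_mean <- if (!is.null(contours)) mean(vapply(contours, `[[`, 0, "L")) else NULL
  iso <- tryCatch(
    iso_concentration_contours(profiles_x, profiles_c,
                               interval = iso_interval, frame = frame,
                               L = L_mean),
    error = function(err) NULL)

  boundary_tests <- list(
    projected = boundary_region_ttests(tr, "projected", bin_interval,
                                       value = "bcd_raw",
                                       center = mean(slant$x_b)),
    contour = boundary_region_ttests(tr, "contour", bin_interval,
                                     value = "bcd_raw",
                                     center = mean(slant$c_b)))

  list(traces = tr, fits = fits, fit_summary = fit_summary,
       boundaries = boundaries, slant = slant, kd = kd, hill = hill,
       io_summary = io_summary, profiles_x = profiles_x,
       profiles_c = profiles_c, noise_x = noise_x, noise_c = noise_c,
       sigma_c = sigma_c, iso = iso, frame = frame,
       boundary_tests = boundary_tests)
}

#' Write a table as TSV with a provenance header
#'
#' Tab-separated values with '.' decimal separator, preceded by comment
#' lines recording the package version and any provenance fields.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param provenance named list written as `# key: value` lines.
#' @param force overwrite an existing file.
#' @export
write_tsv <- function(df, path, provenance = list(), force = FALSE) {
  if (file.exists(path) && !force) {
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bcdgeom %s",
                     as.character(utils::packageVersion("bcdgeom"))), con)
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame (provenance comment lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a midsagittal contour as TSV
#'
#' Columns: `side` (D/V), `index`, `x_um`, `y_um`.
#'
#' @param contour a [midsagittal_contour()].
#' @param path output file.
#' @param force overwrite an existing file.
#' @export
write_contour_tsv <- function(contour, path, force = FALSE) {
  df <- rbind(
    data.frame(side = "D", index = seq_len(nrow(contour$dorsal_arc)),
               x_um = contour$dorsal_arc[, 1], y_um = contour$dorsal_arc[, 2]),
    data.frame(side = "V", index = seq_len(nrow(contour$ventral_arc)),
               x_um = contour$ventral_arc[, 1], y_um = contour$ventral_arc[, 2]))
  write_tsv(df, path, force = force)
}

#' Read a midsagittal contour from TSV
#'
#' @param path file written by [write_contour_tsv()] (or any TSV with
#'   columns `side`, `index`, `x_um`, `y_um`).
#' @param align re-align into the canonical pole frame.
#' @return a [midsagittal_contour()].
#' @export
read_contour_tsv <- function(path, align = FALSE) {
  df <- read_tsv(path)
  d <- df[df$side == "D", ]
  v <- df[df$side == "V", ]
  midsagittal_contour(cbind(d$x_um[order(d$index)], d$y_um[order(d$index)]),
                      cbind(v$x_um[order(v$index)], v$y_um[order(v$index)]),
                      align = align)
}

#' Write a channel raster as TIFF
#'
#' Stores one channel of a rasterized embryo as a 32-bit float TIFF
#' (intensities preserved exactly up to float precision). Requires the
#' `tiff` package.
#'
#' @param image a raster as returned by [rasterize_embryo()].
#' @param path output file.
#' @param channel channel matrix to write.
#' @param force overwrite an existing file.
#' @export
write_raster_tiff <- function(image, path, channel = "bcd", force = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF images")
  }
  if (file.exists(path) && !force) {
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  }
  m <- image[[channel]]
  # TIFF rasters are written top row first; flip so y increases upward
  tiff::writeTIFF(m[rev(seq_len(nrow(m))), , drop = FALSE] / max(m, 1),
                  path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a midsagittal channel image from TIFF
#'
#' Reads a single-channel TIFF into the raster format consumed by
#' [scan_cortical_layer()]. The physical pixel size must be supplied; TIFF
#' rasters store none.
#'
#' @param path TIFF file.
#' @param pixel_scale micrometres per pixel.
#' @param origin_um coordinates of the lower-left pixel corner, um.
#' @param channel name under which to store the channel matrix.
#' @param scale multiplicative intensity rescaling applied after reading.
#' @return a raster list compatible with [scan_cortical_layer()].
#' @export
read_raster_tiff <- function(path, pixel_scale, origin_um = c(0, 0),
                             channel = "bcd", scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF images")
  }
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] * scale
  out <- list(origin_um = origin_um, pixel_scale = pixel_scale)
  out[[channel]] <- m
  out
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates the package stages from a single configuration: generates a
#' synthetic cohort (`synth`), runs the dorsal-ventral analysis suite
#' (`analyze`), and/or runs the 3-D simulation (`simulate`). Artifacts are
#' written under `out_dir` as TSV/JSON with provenance headers carrying the
#' package version, the seed and the configuration.
#'
#' @param config list with optional elements `seed` (integer), `cohort`
#'   (arguments to [cohort_spec()]), `analysis` (arguments to
#'   [analyze_cohort()]) and `simulation` (arguments to [sim_params()]).
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("synth", "analyze", "simulate")`.
#' @param force overwrite existing artifacts.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("synth", "analyze"), force = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  prov <- list(seed = seed,
               config = jsonlite::toJSON(config, auto_unbox = TRUE))
  results <- list()

  if ("synth" %in% stages) {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed)))
    cohort <- generate_cohort(spec)
    results$cohort <- cohort
    write_tsv(cohort_traces(cohort), file.path(out_dir, "traces.tsv"),
              provenance = prov, force = force)
    gt_path <- file.path(out_dir, "ground_truth.json")
    if (file.exists(gt_path) && !force) {
      stop(sprintf("%s exists; use force = TRUE to overwrite", gt_path))
    }
    jsonlite::write_json(lapply(cohort, `[[`, "ground_truth"), gt_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("analyze" %in% stages) {
    if (is.null(results$cohort)) {
      traces <- read_tsv(file.path(out_dir, "traces.tsv"))
      contours <- NULL
    } else {
      traces <- cohort_traces(results$cohort)
      contours <- lapply(results$cohort, `[[`, "contour")
    }
    res <- do.call(analyze_cohort,
                   c(list(traces = traces, contours = contours),
                     config$analysis))
    results$analysis <- res
    write_tsv(res$fits, file.path(out_dir, "fits.tsv"), prov, force)
    write_tsv(res$boundaries, file.path(out_dir, "boundaries.tsv"), prov, force)
    write_tsv(res$noise_x, file.path(out_dir, "noise_x.tsv"), prov, force)
    write_tsv(res$noise_c, file.path(out_dir, "noise_c.tsv"), prov, force)
    if (!is.null(res$iso)) {
      write_tsv(res$iso, file.path(out_dir, "iso_contours.tsv"), prov, force)
    }
    summary <- list(seed = seed, slant = res$slant,
                    io_summary = res$io_summary, sigma_c = as.list(res$sigma_c),
                    fit_summary = res$fit_summary)
    json_path <- file.path(out_dir, "summary.json")
    if (file.exists(json_path) && !force) {
      stop(sprintf("%s exists; use force = TRUE to overwrite", json_path))
    }
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }

  if ("simulate" %in% stages) {
    params <- do.call(sim_params, config$simulation %||% list())
    state <- run_simulation(params)
    prof <- extract_simulated_profiles(state, params)
    results$simulation <- list(state = state, profiles = prof)
    write_tsv(prof, file.path(out_dir, "sim_profiles.tsv"), prov, force)
    write_tsv(state$snapshots, file.path(out_dir, "sim_snapshots.tsv"), prov, force)
  }

  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
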