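#' Parameter-recovery study over seeded synthetic cohorts
#'
#' Repeatedly generates synthetic cohorts at the calibrated study
#' conditions, runs the full analysis pipeline on each, and collects how
#' well the known generator truth is recovered: relative errors of the
#' contour length constants, of K_d and of the Hill coefficient, the
#' dorsal-ventral boundary separations in both distance systems, and the
#' ordering of the positional errors. This is the package's calibration
#' experiment: it quantifies, under known truth, the estimator behaviour of
#' every quantity the comparative analysis reports.
#'
#' @param n_cohorts number of independent cohorts.
#' @param seed base seed; cohort i uses `seed + i`.
#' @param spec_args overrides passed to [cohort_spec()] (e.g. cohort size or
#'   sampling density).
#' @param ... further arguments passed to [analyze_cohort()].
#' @return data.frame with one row per cohort: `relerr_lambda`, `relerr_kd`,
#'   `relerr_n` (mean over sides of absolute relative errors), `delta_x`,
#'   `delta_c` (boundary separations, um), `converges` (|delta_c| <
#'   |delta_x|), `sigma_c_D`, `sigma_c_V` and `sigma_order` (ventral >
#'   dorsal).
#' @export
recovery_study <- function(n_cohorts = 200, seed = 1L,
                           spec_args = list(window_spacing = 2), ...) {
  rows <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    spec <- do.call(cohort_spec, c(spec_args, list(seed = seed + i)))
    cohort <- generate_cohort(spec)
    truth <- cohort[[1]]$ground_truth
    res <- analyze_cohort(cohort_traces(cohort), ...)
    fs <- res$fit_summary
    lam_D <- fs$lambda_mean[fs$side == "D" & fs$axis == "contour"]
    lam_V <- fs$lambda_mean[fs$side == "V" & fs$axis == "contour"]
    kd_D <- res$io_summary$Kd$mean_D
    kd_V <- res$io_summary$Kd$mean_V
    n_D <- res$io_summary$n$mean_D
    n_V <- res$io_summary$n$mean_V
    rows[[i]] <- data.frame(
      cohort = i,
      relerr_lambda = mean(c(abs(lam_D - spec$lambda_c_D) / spec$lambda_c_D,
                             abs(lam_V - spec$lambda_c_V) / spec$lambda_c_V)),
      relerr_kd = mean(c(abs(kd_D - spec$hill_Kd), abs(kd_V - spec$hill_Kd))) /
        spec$hill_Kd,
      relerr_n = mean(c(abs(n_D - spec$hill_n), abs(n_V - spec$hill_n))) /
        spec$hill_n,
      delta_x = res$slant$delta_x$mean,
      delta_c = res$slant$delta_c$mean,
      truth_delta_c = truth$D$c_hb - truth$V$c_hb,
      converges = abs(res$slant$delta_c$mean) < abs(res$slant$delta_x$mean),
      sigma_c_D = res$sigma_c[["D"]],
      sigma_c_V = res$sigma_c[["V"]],
      sigma_order = res$sigma_c[["V"]] > res$sigma_c[["D"]]
    )
  }
  do.call(rbind, rows)
}
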