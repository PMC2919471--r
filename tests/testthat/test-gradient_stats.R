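test_that("exponential fits recover exact gradients and are scale-equivariant", {
  c_pos <- seq(20, 400, by = 4)
  b <- 10 * exp(-c_pos / 104.8)
  fit <- fit_exponential(c_pos, b, axis = "contour")
  expect_equal(fit$lambda, 104.8, tolerance = 1e-9)
  expect_equal(fit$B0, 10, tolerance = 1e-9)

  # two-point analytic case: drop by 1/e over 100 um
  fit2 <- fit_exponential(c(0, 100), c(10, 10 / exp(1)))
  expect_equal(fit2$lambda, 100, tolerance = 1e-12)

  # multiplying intensities rescales B0 only
  fit3 <- fit_exponential(c_pos, 7.3 * b)
  expect_equal(fit3$lambda, fit$lambda, tolerance = 1e-9)
  expect_equal(fit3$B0, 7.3 * fit$B0, tolerance = 1e-9)

  expect_error(fit_exponential(c(1, 2, 3), c(1, 1, 1)), "5 usable")
  expect_error(fit_exponential(c_pos, rev(b)), "decaying")
})

test_that("half-max boundaries are interpolated at the anterior downward crossing", {
  x <- seq(0, 560, by = 2)
  ramp <- ifelse(x < 200, 1, ifelse(x > 300, 0, (300 - x) / 100))
  bd <- find_half_max_boundary(x, x * 1.1, ramp, smooth_span = 1L)
  expect_equal(bd$x_b, 250)
  expect_equal(bd$c_b, 275)

  logi <- 1 / (1 + exp((x - 250) / 15))
  bd2 <- find_half_max_boundary(x, x, logi, smooth_span = 1L)
  expect_equal(bd2$x_b, 250, tolerance = 1e-6)

  expect_error(find_half_max_boundary(x, x, rep(1, length(x))), "cross")
  wig <- logi
  wig[x == 100] <- 0.2   # spurious anterior dip triggers the warning path
  expect_warning(find_half_max_boundary(x, x, wig, smooth_span = 1L),
                 "most anterior")
})

test_that("the measured Kd is the interpolated background-free Bcd level at the boundary", {
  c_pos <- seq(0, 300, by = 0.5)
  b <- 10 * exp(-c_pos / 100)
  expect_equal(measure_kd(c_pos, b, 100 * log(2)), 5.0, tolerance = 1e-5)
  expect_equal(measure_kd(c_pos, rep(4.8, length(c_pos)), 123), 4.8)
  expect_error(measure_kd(c_pos, b, 400), "outside")
})

test_that("the Hill switch has its defining fixed points and fits recover truth", {
  for (n in c(1, 2.5, 5, 9)) expect_equal(hill_function(5, 5, n), 0.5)
  expect_equal(hill_function(10, 5, 5), 32 / 33)
  b <- seq(0.5, 20, by = 0.1)
  expect_true(all(diff(hill_function(b, 5, 5)) > 0))
  expect_equal(hill_function(1e6, 5, 5), 1, tolerance = 1e-6)

  h <- hill_function(b, 5, 5)
  free_fit <- fit_hill(b, h, Kd_mode = "fitted")
  expect_equal(free_fit$Kd, 5, tolerance = 1e-6)
  expect_equal(free_fit$n, 5, tolerance = 1e-6)
  fixed_fit <- fit_hill(b, h, Kd_mode = "fixed", Kd = 5)
  expect_equal(fixed_fit$n, 5, tolerance = 1e-6)

  expect_error(fit_hill(b[1:4], h[1:4]), "at least 8")
  expect_error(fit_hill(b, h, Kd_mode = "fixed"), "supplied")
})

test_that("cross-embryo intensity noise estimates the generating CV", {
  # identical embryos carry zero noise
  tr0 <- do.call(rbind, lapply(1:5, function(e) {
    data.frame(embryo = e, side = "D", x_um = 1:50, c_um = 1:50, bcd_raw = 2)
  }))
  np0 <- intensity_noise_profile(tr0, "projected", interval = 10)
  expect_true(all(np0$noise == 0))

  # multiplicative noise with CV 0.10 across 200 embryos reads back as ~0.10
  set.seed(42)
  tr <- do.call(rbind, lapply(1:200, function(e) {
    data.frame(embryo = e, side = "D", x_um = seq(5, 95, by = 10),
               c_um = seq(5, 95, by = 10),
               bcd_raw = 8 * (1 + rnorm(1, 0, 0.10)))
  }))
  np <- intensity_noise_profile(tr, "projected", interval = 10)
  expect_equal(mean(np$noise), 0.10, tolerance = 0.1)

  # bins below the embryo-count threshold are dropped
  np2 <- intensity_noise_profile(tr0[tr0$embryo <= 2, ], "projected",
                                 interval = 10, min_embryos = 3L)
  expect_equal(nrow(np2), 0L)
})

test_that("positional error equals lambda times relative noise for exponential profiles", {
  lambda <- 100
  centers <- seq(100, 300, by = 10)   # span 5 bins = 50 um <= lambda/2
  prof <- data.frame(side = "D", bin_center = centers,
                     mean = 20 * exp(-centers / lambda))
  prof$sd <- 0.1 * prof$mean
  pe <- positional_error(prof, span = 5L)
  inner <- pe[3:(nrow(pe) - 2), ]
  expect_equal(inner$sigma_c, rep(lambda * 0.1, nrow(inner)), tolerance = 0.02)

  prof0 <- prof
  prof0$sd <- 0
  expect_true(all(positional_error(prof0)$sigma_c == 0, na.rm = TRUE))

  flat <- data.frame(side = "D", bin_center = centers, mean = 1, sd = 0.1)
  expect_true(all(is.na(positional_error(flat)$sigma_c)))
})

test_that("bootstrap SDs are reproducible and match the analytic SE of a mean", {
  same <- as.list(rep(3.3, 10))
  bs0 <- bootstrap_sd(function(ch) mean(unlist(ch)), same, 200, seed = 5)
  expect_equal(bs0$sd, 0)

  set.seed(8)
  sample100 <- as.list(rnorm(100))
  stat <- function(ch) mean(unlist(ch))
  bs <- bootstrap_sd(stat, sample100, 1000, seed = 21)
  se <- stats::sd(unlist(sample100)) / sqrt(100)
  expect_equal(bs$sd, se, tolerance = 0.2)
  bs2 <- bootstrap_sd(stat, sample100, 1000, seed = 21)
  expect_identical(bs$sd, bs2$sd)

  expect_error(bootstrap_sd(stat, sample100[1:2], 1000), ">= 3")
  expect_error(bootstrap_sd(stat, sample100, 50), ">= 100")
  # statistics failing on most replicates abort
  flaky <- function(ch) stop("nope")
  expect_error(bootstrap_sd(flaky, sample100, 100, seed = 1), "failed on")
})

test_that("the side-comparison t-test matches the closed-form pooled-variance oracle", {
  d <- c(1, 2, 3, 4, 5)
  v <- c(2, 3, 4, 5, 6)
  res <- compare_sides_ttest(d, v)
  # textbook pooled-variance computation
  sp2 <- ((length(d) - 1) * stats::var(d) + (length(v) - 1) * stats::var(v)) /
    (length(d) + length(v) - 2)
  t_oracle <- (mean(d) - mean(v)) / sqrt(sp2 * (1 / length(d) + 1 / length(v)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(d) + length(v) - 2)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)

  same <- compare_sides_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)

  set.seed(2)
  a <- rnorm(28, 0, 1)
  b <- rnorm(28, 3, 1)
  expect_lt(compare_sides_ttest(a, b)$p, 1e-6)
})

test_that("iso-concentration contours vanish for symmetric profiles and capture slant", {
  pos <- seq(5.5 / 2, 500, by = 5.5)
  mk <- function(b0, lam) {
    rbind(data.frame(side = "D", axis = "projected", bin_center = pos,
                     mean = b0 * exp(-pos / lam)),
          data.frame(side = "V", axis = "projected", bin_center = pos,
                     mean = b0 * exp(-pos / lam)))
  }
  sym <- iso_concentration_contours(mk(50, 100), mk(50, 112),
                                    thresholds = c(5, 10, 20))
  expect_equal(sym$delta_x, rep(0, 3), tolerance = 1e-9)
  expect_equal(sym$delta_c, rep(0, 3), tolerance = 1e-9)

  # dorsal reaches a threshold farther from the pole in x than in c when the
  # contour stretch compensates the projected shift
  profx <- rbind(
    data.frame(side = "D", bin_center = pos, mean = 50 * exp(-pos / 100)),
    data.frame(side = "V", bin_center = pos, mean = 50 * exp(-pos / 100) * 0.8))
  profc <- rbind(
    data.frame(side = "D", bin_center = pos, mean = 50 * exp(-pos / 110)),
    data.frame(side = "V", bin_center = pos, mean = 50 * exp(-pos / 110) * 0.95))
  iso <- iso_concentration_contours(profx, profc, thresholds = c(2, 5, 10))
  expect_true(all(iso$delta_x > iso$delta_c))
})

test_that("target slant statistics separate projected from contour differences", {
  set.seed(9)
  n <- 20
  bnd <- rbind(
    data.frame(embryo = 1:n, side = "D", x_b = rnorm(n, 248.7, 5),
               c_b = rnorm(n, 284.6, 5)),
    data.frame(embryo = 1:n, side = "V", x_b = rnorm(n, 232.2, 5),
               c_b = rnorm(n, 279.1, 5)))
  sl <- target_slant(bnd)
  expect_lt(abs(sl$delta_x$mean - 16.5), 6)
  expect_gt(abs(sl$delta_x$mean), abs(sl$delta_c$mean))
  expect_lt(sl$delta_x$p, 0.001)

  # symmetric cohort: no slant
  bnd0 <- rbind(
    data.frame(embryo = 1:n, side = "D", x_b = rnorm(n, 240, 5),
               c_b = rnorm(n, 280, 5)),
    data.frame(embryo = 1:n, side = "V", x_b = rnorm(n, 240, 5),
               c_b = rnorm(n, 280, 5)))
  sl0 <- target_slant(bnd0)
  expect_gt(sl0$delta_x$p, 0.01)

  expect_warning(target_slant(bnd[-1, ]), "unpaired")
})
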