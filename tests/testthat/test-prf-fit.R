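make_truth_and_data <- function(n_vertices = 12L, apertures = test_apertures()) {
  surf <- build_surface(c(V1 = n_vertices), spacing = 2)
  tpl <- generate_template_map(surf)
  tcs <- vapply(seq_len(n_vertices), function(v) {
    predict_timecourse(c(x0 = tpl$x0[v], y0 = tpl$y0[v], sigma = tpl$sigma[v]),
                       apertures)
  }, numeric(nrow(apertures$frames)))
  list(surface = surf, truth = tpl, timecourses = tcs)
}

test_that("smoothing has the configured FWHM and respects its contracts", {
  surf <- build_surface(c(V1 = 441L))  # 21 x 21 lattice, 1 mm spacing
  const <- rep(3.7, 441)
  expect_equal(smooth_map(surf, const, fwhm = 3), const)
  grad <- surf$x + 2 * surf$y
  expect_identical(smooth_map(surf, grad, fwhm = 0), grad)
  expect_equal(mean(smooth_map(surf, grad, fwhm = 3)), mean(grad),
               tolerance = 1e-10)
  # impulse response: half the peak at half the FWHM from the centre
  centre <- which(surf$x == 10 & surf$y == 10)
  imp <- rep(0, 441)
  imp[centre] <- 1
  sm <- smooth_map(surf, imp, fwhm = 3)
  neighbour <- which(surf$x == 11.5 & surf$y == 10)  # no vertex at 1.5 mm
  at <- function(dx) exp(-dx^2 / (2 * (3 / (2 * sqrt(2 * log(2))))^2))
  expect_equal(sm[surf$x == 11 & surf$y == 10] / sm[centre], at(1),
               tolerance = 1e-9)
  expect_equal(sm[surf$x == 12 & surf$y == 10] / sm[centre], at(2),
               tolerance = 1e-9)
})

test_that("circular smoothing averages across the wrap-around", {
  surf <- build_surface(c(V1 = 4L), spacing = 1)
  vals <- c(pi - 0.1, -pi + 0.1, pi - 0.1, -pi + 0.1)
  sm <- smooth_map(surf, vals, fwhm = 6, circular = TRUE)
  expect_true(all(abs(abs(sm) - pi) < 0.11))  # stays near pi, never near 0
})

test_that("coarse fit recovers exact grid points from noise-free data", {
  ap <- test_apertures()
  cfg <- fit_config(x0_grid = seq(-8, 8, by = 2), y0_grid = seq(-8, 8, by = 2),
                    sigma_grid = c(0.5, 1, 2), coarse_fwhm = 0, final_fwhm = 0)
  surf <- build_surface(c(V1 = 6L), spacing = 2)
  truth <- cbind(x0 = c(-4, 0, 6, 2, -2, 4), y0 = c(2, -6, 0, 4, -4, 2),
                 sigma = c(1, 2, 0.5, 1, 2, 1))
  tcs <- vapply(seq_len(6), function(v) {
    predict_timecourse(truth[v, ], ap)
  }, numeric(480))
  cf <- coarse_fit(tcs, surf, ap, cfg)
  expect_equal(cf$x0, unname(truth[, "x0"]))
  expect_equal(cf$y0, unname(truth[, "y0"]))
  expect_equal(cf$sigma, unname(truth[, "sigma"]))
  expect_true(all(cf$r2 > 0.999))
})

test_that("pure-noise series rarely exceed the coarse inclusion threshold", {
  ap <- test_apertures()
  cfg <- fit_config(x0_grid = seq(-8, 8, by = 4), y0_grid = seq(-8, 8, by = 4),
                    sigma_grid = c(1, 2), coarse_fwhm = 0, final_fwhm = 0)
  surf <- build_surface(c(V1 = 40L), spacing = 2)
  set.seed(31)
  noise <- matrix(rnorm(480 * 40), 480, 40)
  cf <- coarse_fit(noise, surf, ap, cfg)
  expect_gt(mean(cf$r2 < 0.05), 0.8)
})

test_that("a constant series is flagged unfit with zero R-squared", {
  ap <- test_apertures()
  cfg <- fit_config(x0_grid = 0, y0_grid = 0, sigma_grid = 1,
                    coarse_fwhm = 0, final_fwhm = 0)
  surf <- build_surface(c(V1 = 2L), spacing = 2)
  tcs <- cbind(rep(1, 480),
               predict_timecourse(c(x0 = 0, y0 = 0, sigma = 1), ap))
  cf <- coarse_fit(tcs, surf, ap, cfg)
  expect_equal(cf$r2[1], 0)
  expect_false(attr(cf, "fitted")[1])
  expect_true(attr(cf, "fitted")[2])
})

test_that("fine fit recovers off-grid truth and excludes poor coarse fits", {
  ap <- test_apertures()
  cfg <- fit_config(x0_grid = seq(-8, 8, by = 2), y0_grid = seq(-8, 8, by = 2),
                    sigma_grid = c(0.5, 1, 2), coarse_fwhm = 0, final_fwhm = 0)
  truth <- cbind(x0 = c(2.3, -1.2, 5.1), y0 = c(-1.7, 3.4, 0.6),
                 sigma = c(1.4, 0.8, 2.2))
  tcs <- vapply(seq_len(3), function(v) predict_timecourse(truth[v, ], ap),
                numeric(480))
  tcs <- cbind(tcs, rnorm(480))  # a pure-noise vertex stays at its coarse fit
  surf4 <- build_surface(c(V1 = 4L), spacing = 2)
  cf <- coarse_fit(tcs, surf4, ap, cfg)
  ff <- fine_fit(tcs, cf, surf4, ap, cfg)
  expect_true(all(abs(ff$x0[1:3] - truth[, "x0"]) < 0.05))
  expect_true(all(abs(ff$y0[1:3] - truth[, "y0"]) < 0.05))
  expect_true(all(abs(ff$sigma[1:3] - truth[, "sigma"]) / truth[, "sigma"] < 0.05))
  expect_true(all(attr(ff, "refined")[1:3]))
  expect_false(attr(ff, "refined")[4])
  expect_equal(ff$x0[4], cf$x0[4])
  # same objective, seeded at the coarse solution: R2 never decreases
  expect_true(all(ff$r2[1:3] >= cf$r2[1:3] - 1e-12))
})

test_that("fitted amplitude scales linearly with the signal", {
  ap <- test_apertures()
  cfg <- fit_config(x0_grid = seq(-8, 8, by = 2), y0_grid = seq(-8, 8, by = 2),
                    sigma_grid = c(0.5, 1, 2), coarse_fwhm = 0, final_fwhm = 0,
                    tol = 1e-10, maxit = 1000L)
  surf <- build_surface(c(V1 = 2L), spacing = 2)
  base <- predict_timecourse(c(x0 = 2.3, y0 = -1.7, sigma = 1.4, amplitude = 1),
                             ap, normalize = FALSE)
  tcs <- cbind(base, 2 * base)
  cf <- coarse_fit(tcs, surf, ap, cfg)
  ff <- fine_fit(tcs, cf, surf, ap, cfg)
  expect_equal(ff$amplitude[2] / ff$amplitude[1], 2, tolerance = 1e-2)
  expect_lt(abs(ff$x0[1] - ff$x0[2]), 0.01)
  expect_lt(abs(ff$y0[1] - ff$y0[2]), 0.01)
})

test_that("visual field coverage is a mean of unit Gaussian profiles", {
  m <- data.frame(x0 = c(3, 3), y0 = c(-2, -2), sigma = c(1.5, 1.5))
  one <- visual_field_coverage(m, vertices = 1L, n = 41L)
  both <- visual_field_coverage(m, n = 41L)
  expect_equal(one$coverage, both$coverage)
  peak <- arrayInd(which.max(one$coverage), dim(one$coverage))
  expect_equal(one$x[peak[1]], 3, tolerance = 0.5)
  expect_equal(one$y[peak[2]], -2, tolerance = 0.5)
  expect_true(all(one$coverage >= 0 & one$coverage <= 1))
  expect_error(visual_field_coverage(m, vertices = integer(0)), "empty")
})

test_that("pRF size by eccentricity bins and recovers a linear relation", {
  m <- data.frame(x0 = c(0.5, 1.5, 2.5), y0 = 0, sigma = c(0.5, 1.5, 2.5))
  m$ecc <- sqrt(m$x0^2 + m$y0^2)
  tab <- prf_size_by_eccentricity(m, band_width = 1)
  expect_equal(tab$mean_sigma, tab$band_center)
  one <- prf_size_by_eccentricity(m[2, ], band_width = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_sigma, 1.5)
  # generator slope recovered from binned means
  surf <- build_surface(c(V1 = 900L))
  tpl <- generate_template_map(surf, sigma_intercept = 0.5, sigma_slope = 0.15)
  tab2 <- prf_size_by_eccentricity(tpl, band_width = 1)
  fitted <- stats::lm(mean_sigma ~ band_center, data = tab2)
  expect_equal(unname(coef(fitted)[2]), 0.15, tolerance = 0.02)
})
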