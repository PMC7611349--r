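test_that("de-meaning removes the shared pattern, linearly and circularly", {
  expect_equal(demean_maps(matrix(c(1, 3), 2, 1)), matrix(c(-1, 1), 2, 1))
  same <- matrix(rep(c(2, 5, 8), 3), 3, byrow = TRUE)
  expect_true(all(demean_maps(same) == 0))
  deg <- pi / 180
  two <- matrix(c(10 * deg, 350 * deg), 2, 1)
  res <- demean_maps(two, circular = TRUE)
  expect_equal(as.numeric(res), c(10 * deg, -10 * deg), tolerance = 1e-12)
  expect_error(demean_maps(matrix(1, 1, 3)), "2 subjects")
})

test_that("adding a fixed template to every subject changes no correlation", {
  set.seed(51)
  x <- matrix(rnorm(8 * 200), 8, 200)
  tplt <- rnorm(200, sd = 5)
  shifted <- sweep(x, 2, tplt, "+")
  r0 <- pair_correlation(demean_maps(x)[1, ], demean_maps(x)[2, ])
  r1 <- pair_correlation(demean_maps(shifted)[1, ], demean_maps(shifted)[2, ])
  expect_equal(r0, r1, tolerance = 1e-9)
  # circular version with wrapped template
  a <- wrap_angle(matrix(rnorm(6 * 200, sd = 0.4), 6, 200))
  ash <- wrap_angle(sweep(a, 2, runif(200, -pi, pi), "+"))
  c0 <- pair_correlation(demean_maps(a, TRUE)[1, ], demean_maps(a, TRUE)[2, ],
                         method = "circular")
  c1 <- pair_correlation(demean_maps(ash, TRUE)[1, ],
                         demean_maps(ash, TRUE)[2, ], method = "circular")
  expect_equal(c0, c1, tolerance = 1e-9)
})

test_that("circular correlation is exact and rotation invariant", {
  set.seed(52)
  a <- runif(500, -pi, pi)
  expect_equal(pair_correlation(a, a, method = "circular"), 1)
  expect_equal(pair_correlation(a, wrap_angle(a + 1.234), method = "circular"),
               1, tolerance = 1e-9)
  b <- runif(10000, -pi, pi)
  a2 <- runif(10000, -pi, pi)
  expect_lt(abs(pair_correlation(a2, b, method = "circular")), 0.05)
})

test_that("rank correlation is invariant to monotone transforms", {
  set.seed(53)
  x <- rnorm(300)
  y <- 0.5 * x + rnorm(300)
  expect_equal(pair_correlation(x, y), pair_correlation(exp(x), y^3 + y))
})

test_that("degenerate correlation inputs are flagged or rejected", {
  expect_warning(r <- pair_correlation(rep(1, 10), rnorm(10)), "zero variance")
  expect_true(is.na(r))
  expect_error(pair_correlation(1:2, 1:2), "3 paired")
  expect_error(pair_correlation(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("Fisher-z group averaging follows its closed form", {
  expect_equal(group_mean_correlation(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(group_mean_correlation(c(0, 0)), 0)
  expect_equal(group_mean_correlation(c(0.2, 0.6)),
               tanh((atanh(0.2) + atanh(0.6)) / 2))
  expect_equal(group_mean_correlation(c(0.2, 0.6), transform = "z"),
               (atanh(0.2) + atanh(0.6)) / 2)
  expect_error(group_mean_correlation(c(0.5, 1)), "infinite")
  # round trip identity on the usable range
  r <- seq(-0.999, 0.999, length.out = 41)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)
})

test_that("the correlation difference formula is exact and antisymmetric", {
  expect_equal(delta_r(0.53, 0.47), 12, tolerance = 1e-12)
  expect_equal(delta_r(0.06, 0), 12, tolerance = 1e-12)
  expect_identical(delta_r(0.5, 0.5), 0)
  for (ab in list(c(0.3, 0.1), c(-0.2, 0.4), c(0.9, 0.85))) {
    expect_equal(delta_r(ab[1], ab[2]), -delta_r(ab[2], ab[1]))
  }
  expect_error(delta_r(1.2, 0), "\\[-1, 1\\]")
})

test_that("bootstrap collapses correctly on degenerate inputs", {
  res <- bootstrap_delta_r(rep(0.8, 5), rep(0.2, 4), n_boot = 500, seed = 1)
  expect_equal(res$delta_r, 120, tolerance = 1e-9)
  expect_true(all(abs(res$draws - 120) < 1e-9))
  expect_equal(res$p, 0)
  expect_equal(c(res$ci_low, res$ci_high), c(120, 120), tolerance = 1e-9)
  same <- bootstrap_delta_r(rep(0.3, 5), rep(0.3, 4), n_boot = 500, seed = 1)
  expect_true(all(same$draws == 0))
  expect_equal(same$p, 1)
  expect_error(bootstrap_delta_r(numeric(0), rep(0.3, 4)), "2 pairs")
  expect_warning(bootstrap_delta_r(rep(c(0.3, 0.4), 3), rep(0.2, 4),
                                   n_boot = 50, seed = 1), "coarse")
})

test_that("hierarchy trend slopes follow exact OLS on three regions", {
  ht <- hierarchy_trend(list(rep(10, 100), rep(20, 100), rep(30, 100)))
  expect_equal(ht$slope, 10)
  expect_true(all(ht$slopes == 10))
  expect_equal(ht$p, 0)
  flat <- hierarchy_trend(list(rep(4, 50), rep(4, 50), rep(4, 50)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  set.seed(54)
  iid <- hierarchy_trend(list(rnorm(4000), rnorm(4000), rnorm(4000)))
  expect_equal(iid$p, 0.5, tolerance = 0.05)
  expect_error(hierarchy_trend(list(rnorm(10), rnorm(9), rnorm(10))),
               "iteration counts")
})

test_that("identical twins give a zero permutation p for correlations", {
  co <- small_cohort(sizes = c(V1 = 120L), n_mz = 5L, n_dz = 4L,
                     rho_mz = 1, rho_dz = 0, seed = 55L)
  res <- permutation_correlation_test(co, "ecc", region = "V1", group = "MZ",
                                      n_perm = 200, seed = 2)
  expect_equal(res$p, 0)
  expect_gt(res$observed, 0.99)
  expect_error(permutation_correlation_test(co, "ecc", region = "V1",
                                            group = "MZ", n_perm = 0),
               "n_perm")
})

test_that("subsampled correlation analysis runs on non-adjacent vertices", {
  co <- small_cohort(sizes = c(V1 = 400L), n_mz = 5L, n_dz = 4L, seed = 56L)
  verts <- subsample_vertices(co$surface, "V1", min_dist = 8, seed = 1)
  cs <- cohort_correlations(co, "sigma", vertices = verts)
  expect_equal(nrow(cs), 9L)
  expect_true(all(is.finite(cs$r)))
})

test_that("transformation magnitudes degenerate to undefined correlations", {
  co <- small_cohort(n_mz = 3L, n_dz = 3L, seed = 57L)
  tm <- transformation_magnitude(co, "V1")
  expect_true(all(tm$subjects$mean_displacement == 0))
  expect_true(all(is.na(tm$groups$r)))
})

test_that("multidimensional heritability hits its structural limits", {
  co <- small_cohort(sizes = c(V1 = 600L), n_mz = 8L, n_dz = 7L,
                     rho_mz = 1, rho_dz = 0.5, seed = 58L)
  ph <- demean_maps(cohort_parameter_matrix(co, "ecc",
                                            which(co$surface$region == "V1")))
  h <- multidim_h2(ph, cohort_meta(co), n_boot = 200, seed = 1)
  expect_gt(h$h2, 0.85)
  co0 <- small_cohort(sizes = c(V1 = 600L), n_mz = 8L, n_dz = 7L,
                      rho_mz = 0.5, rho_dz = 0.5, seed = 59L)
  ph0 <- demean_maps(cohort_parameter_matrix(co0, "ecc",
                                             which(co0$surface$region == "V1")))
  h0 <- multidim_h2(ph0, cohort_meta(co0), n_boot = 200, seed = 1)
  expect_lt(h0$h2, 0.3)
  expect_lte(h0$ci_low, max(h0$h2, 0.05))
  expect_error(multidim_h2(matrix(1, 10, 5),
                           data.frame(pair_id = rep(1:5, each = 2),
                                      zygosity = rep(c("MZ", "DZ"),
                                                     c(6, 4)))),
               "constant")
})
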