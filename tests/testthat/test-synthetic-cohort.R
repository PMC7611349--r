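test_that("perfect intra-pair correlation makes co-twins identical", {
  co <- small_cohort(n_mz = 2L, n_dz = 2L, rho_mz = 1, rho_dz = 1, seed = 3L)
  pairs <- cohort_pairs(co)
  for (p in seq_len(nrow(pairs))) {
    a <- co$subjects[[pairs$i[p]]]
    b <- co$subjects[[pairs$j[p]]]
    expect_equal(a$prf$polar, b$prf$polar, tolerance = 1e-12)
    expect_equal(a$prf$sigma, b$prf$sigma, tolerance = 1e-12)
    expect_equal(a$prf$ecc, b$prf$ecc, tolerance = 1e-12)
    expect_identical(a$region_labels, b$region_labels)
  }
})

test_that("target intra-pair correlations are realized empirically", {
  surf <- build_surface(c(V3 = 8100L))
  tpl <- generate_template_map(surf)
  # away from the fovea, additive eccentricity noise cannot cross zero, so
  # the stored deviations equal the generated Gaussian fields (>3000 vertices)
  far <- which(tpl$ecc > 2)
  expect_gt(length(far), 3000L)
  cfg <- generator_config(n_mz = 5L, n_dz = 5L, rho_mz = 0.53, rho_dz = 0.47,
                          seed = 11L)
  co <- generate_twin_cohort(surf, tpl, cfg)
  pairs <- cohort_pairs(co)
  for (p in seq_len(nrow(pairs))) {
    target <- if (pairs$zygosity[p] == "MZ") 0.53 else 0.47
    for (param in c("polar", "ecc", "sigma")) {
      da <- deviation_field(co$subjects[[pairs$i[p]]], tpl, param)
      db <- deviation_field(co$subjects[[pairs$j[p]]], tpl, param)
      if (param != "sigma") {
        da <- da[far]
        db <- db[far]
      }
      expect_lt(abs(cor(da, db) - target), 0.05,
                label = sprintf("%s %s correlation error",
                                pairs$pair_id[p], param))
    }
  }
})

test_that("uncorrelated pairs give near-zero deviation correlations", {
  surf <- build_surface(c(V3 = 3409L))
  tpl <- generate_template_map(surf)
  rs <- numeric(0)
  for (seed in 1:10) {
    cfg <- generator_config(n_mz = 1L, n_dz = 1L, rho_mz = 0, rho_dz = 0,
                            seed = seed)
    co <- generate_twin_cohort(surf, tpl, cfg)
    pairs <- cohort_pairs(co)
    for (p in seq_len(nrow(pairs))) {
      rs <- c(rs, cor(deviation_field(co$subjects[[pairs$i[p]]], tpl, "sigma"),
                      deviation_field(co$subjects[[pairs$j[p]]], tpl, "sigma")))
    }
  }
  # r ~ N(0, 1/sqrt(3409)): generous per-draw bound plus a tight mean bound
  expect_true(all(abs(rs) < 0.09))
  expect_lt(abs(mean(rs)), 0.015)
})

test_that("circular fields stay in (-pi, pi] and sigma stays positive", {
  co <- small_cohort(seed = 5L)
  for (s in co$subjects) {
    expect_true(all(s$prf$polar > -pi & s$prf$polar <= pi))
    expect_true(all(s$prf$sigma > 0))
    pe <- prf_polar_ecc(s$prf$x0, s$prf$y0)
    expect_equal(s$prf$polar, pe$polar, tolerance = 1e-9)
    expect_equal(s$prf$ecc, pe$ecc, tolerance = 1e-9)
  }
})

test_that("a fixed seed fixes the whole cohort", {
  a <- small_cohort(seed = 9L)
  b <- small_cohort(seed = 9L)
  expect_identical(cohort_parameter_matrix(a, "polar"),
                   cohort_parameter_matrix(b, "polar"))
  expect_identical(cohort_parameter_matrix(a, "sigma"),
                   cohort_parameter_matrix(b, "sigma"))
  c3 <- small_cohort(seed = 10L)
  expect_false(identical(cohort_parameter_matrix(a, "sigma"),
                         cohort_parameter_matrix(c3, "sigma")))
})

test_that("invalid generator settings are rejected", {
  expect_error(generator_config(rho_mz = 1.2), "\\[-1, 1\\]")
  expect_error(generator_config(noise_sd = c(polar = -1, ecc = 1, sigma = 1,
                                             curvature = 1, thickness = 1)),
               ">= 0")
})

test_that("morphology maps share the pair-correlated construction", {
  co <- small_cohort(n_mz = 2L, n_dz = 2L, rho_mz = 1, rho_dz = 1, seed = 2L)
  co <- generate_morphology_maps(co)
  pairs <- cohort_pairs(co)
  for (p in seq_len(nrow(pairs))) {
    expect_equal(co$subjects[[pairs$i[p]]]$curvature,
                 co$subjects[[pairs$j[p]]]$curvature, tolerance = 1e-12)
  }
  # zero thickness SD collapses every subject onto the mean pattern
  co2 <- small_cohort(n_mz = 2L, n_dz = 2L, seed = 2L)
  cfg <- co2$config
  cfg$noise_sd["thickness"] <- 0
  co2 <- generate_morphology_maps(co2, cfg)
  th <- cohort_parameter_matrix(co2, "thickness")
  expect_equal(max(apply(th, 2, sd)), 0)
})

test_that("morphology correlations recover their target", {
  # many pairs, so that subtracting the sample-mean pattern (the only
  # estimate of the shared folding template) barely attenuates
  surf <- build_surface(c(V3 = 3409L))
  tpl <- generate_template_map(surf)
  cfg <- generator_config(n_mz = 100L, n_dz = 100L, rho_mz = 0.6,
                          rho_dz = 0.4, seed = 21L)
  co <- generate_morphology_maps(generate_twin_cohort(surf, tpl, cfg))
  curv <- cohort_parameter_matrix(co, "curvature")
  dev <- sweep(curv, 2, colMeans(curv))
  pairs <- cohort_pairs(co)
  check <- c(1:6, 101:106)  # a handful of MZ and DZ pairs
  for (p in check) {
    target <- if (pairs$zygosity[p] == "MZ") 0.6 else 0.4
    expect_lt(abs(cor(dev[pairs$i[p], ], dev[pairs$j[p], ]) - target), 0.05,
              label = sprintf("%s curvature correlation error",
                              pairs$pair_id[p]))
  }
})

test_that("alignment displacements behave at their degenerate settings", {
  co <- small_cohort(n_mz = 2L, n_dz = 2L, seed = 4L)
  co0 <- generate_alignment_coordinates(co, displacement_sd = 0)
  for (s in co0$subjects) {
    expect_identical(s$native_coord, s$aligned_coord)
  }
  # uniform translation: every per-vertex displacement equals its norm
  co$subjects[[1]]$native_coord <- co$subjects[[1]]$aligned_coord +
    matrix(rep(c(3, 4), each = nrow(co$surface)), ncol = 2)
  tm <- transformation_magnitude(co, "V1")
  expect_equal(tm$subjects$mean_displacement[1], 5, tolerance = 1e-12)
  expect_error(generate_alignment_coordinates(co, displacement_sd = -1),
               ">= 0")
})

test_that("uncoupled alignment magnitudes are uncorrelated between twins", {
  co <- small_cohort(sizes = c(V1 = 64L), n_mz = 150L, n_dz = 2L, seed = 6L)
  co <- generate_alignment_coordinates(co, displacement_sd = 1.5,
                                       pair_coupling = 0, seed = 13L)
  tm <- transformation_magnitude(co, "V1")
  r <- tm$groups$r[tm$groups$zygosity == "MZ"]
  expect_lt(abs(r), 0.2)  # ~2.5 SE at 150 pairs
})
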