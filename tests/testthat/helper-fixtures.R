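# Shared fixtures, built once per test run.

small_surface <- function(sizes = c(V1 = 100L, V2 = 100L, V3 = 100L)) {
  build_surface(sizes)
}

small_cohort <- function(sizes = c(V1 = 100L, V2 = 100L, V3 = 100L),
                         n_mz = 5L, n_dz = 4L, rho_mz = 0.6, rho_dz = 0.4,
                         seed = 1L, ...) {
  surf <- build_surface(sizes)
  tpl <- generate_template_map(surf)
  cfg <- generator_config(n_mz = n_mz, n_dz = n_dz, rho_mz = rho_mz,
                          rho_dz = rho_dz, seed = seed, ...)
  generate_twin_cohort(surf, tpl, cfg)
}

# test apertures at reduced spatial resolution (fast but well resolved)
test_apertures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_apertures(stim_config(resolution = 41L))
    cache
  }
})

# deviation of a subject's map from the template, on the generator's scale
deviation_field <- function(subject, template, parameter) {
  switch(parameter,
         polar = wrap_angle(subject$prf$polar - template$polar),
         ecc = subject$prf$ecc - template$ecc,
         sigma = log(subject$prf$sigma / template$sigma),
         subject_parameter(subject, parameter))
}
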