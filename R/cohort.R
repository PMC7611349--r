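#' Generator configuration for synthetic twin cohorts
#'
#' Encodes the statistical structure the heritability analysis assumes: twin
#' pairs whose map deviations from a shared template are correlated within
#' pairs, more strongly for monozygotic (MZ) than dizygotic (DZ) pairs when
#' the trait is heritable.
#'
#' Intra-pair correlations can be a single number applied to every parameter
#' or a named vector with entries per parameter
#' (\code{polar}, \code{ecc}, \code{sigma}, \code{curvature},
#' \code{thickness}, \code{boundary}).
#'
#' @param n_mz,n_dz Number of MZ and DZ twin pairs (defaults 19 and 14).
#' @param rho_mz,rho_dz Target intra-pair correlations of the deviation
#'   fields, in [-1, 1]; \code{rho_mz >= rho_dz} for heritable scenarios.
#' @param noise_sd Named vector of deviation standard deviations:
#'   \code{polar} (radians), \code{ecc} (degrees), \code{sigma}
#'   (log-units; pRF size deviations are multiplicative so that sizes stay
#'   positive), \code{curvature} (unitless), \code{thickness} (mm).
#' @param boundary_jitter_sd SD in mm of the per-subject displacement of
#'   region boundaries, producing individual region delineations for the
#'   overlap analysis (default 2 mm).
#' @param smoothing_fwhm Optional FWHM in mm of a Gaussian kernel applied to
#'   the deviation fields; 0 (default) keeps them spatially white. No
#'   reference value exists for the autocorrelation length of individual map
#'   deviations, so white noise is the default and smoothness is opt-in.
#' @param seed Master integer seed; every generation stage draws from an
#'   independent substream derived from it.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_mz = 19L, n_dz = 14L,
                             rho_mz = 0.6, rho_dz = 0.4,
                             noise_sd = c(polar = 0.3, ecc = 0.5, sigma = 0.2,
                                          curvature = 0.15, thickness = 0.25),
                             boundary_jitter_sd = 2,
                             smoothing_fwhm = 0,
                             seed = 1L) {
  if (n_mz < 1 || n_dz < 1) stop_invalid("need at least one pair per group")
  if (any(abs(c(unlist(rho_mz), unlist(rho_dz))) > 1)) {
    stop_invalid("intra-pair correlations must lie in [-1, 1]")
  }
  if (any(noise_sd < 0) || boundary_jitter_sd < 0 || smoothing_fwhm < 0) {
    stop_invalid("standard deviations and FWHM must be >= 0")
  }
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 rho_mz = rho_mz, rho_dz = rho_dz, noise_sd = noise_sd,
                 boundary_jitter_sd = boundary_jitter_sd,
                 smoothing_fwhm = smoothing_fwhm, seed = as.integer(seed)),
            class = "generator_config")
}

rho_for <- function(rho, parameter) {
  if (length(rho) == 1L && is.null(names(rho))) return(as.numeric(rho))
  if (!is.null(names(rho)) && parameter %in% names(rho)) {
    return(as.numeric(rho[[parameter]]))
  }
  if (length(rho) == 1L) return(as.numeric(rho))
  stop_invalid("no intra-pair correlation given for parameter '", parameter, "'")
}

sd_for <- function(noise_sd, parameter) {
  if (!parameter %in% names(noise_sd)) {
    stop_invalid("no noise SD given for parameter '", parameter, "'")
  }
  as.numeric(noise_sd[[parameter]])
}

# One pair of deviation fields with exact expected intra-pair correlation rho:
# each twin mixes a shared and a unique i.i.d. Gaussian component with
# weights sqrt(|rho|) and sqrt(1 - |rho|); negative rho flips the shared
# component's sign for the second twin.
pair_deviations <- function(n, rho, sd) {
  if (abs(rho) > 1) stop_invalid("|rho| must be <= 1")
  if (sd == 0) return(list(a = numeric(n), b = numeric(n)))
  s <- stats::rnorm(n, 0, sd)
  w_s <- sqrt(abs(rho))
  w_u <- sqrt(1 - abs(rho))
  list(a = w_s * s + w_u * stats::rnorm(n, 0, sd),
       b = sign(rho + (rho == 0)) * w_s * s + w_u * stats::rnorm(n, 0, sd))
}

region_boundaries <- function(surface) {
  regs <- unique(surface$region)
  if (length(regs) < 2L) return(list(regions = regs, bounds = numeric(0)))
  b <- vapply(seq_len(length(regs) - 1L), function(k) {
    (max(surface$y[surface$region == regs[k]]) +
       min(surface$y[surface$region == regs[k + 1L]])) / 2
  }, numeric(1))
  list(regions = regs, bounds = b)
}

jittered_labels <- function(surface, rb, delta) {
  if (length(rb$bounds) == 0L) return(surface$region)
  b <- sort(rb$bounds + delta)
  rb$regions[1L + findInterval(surface$y, b)]
}

#' Generate a twin cohort of retinotopic maps
#'
#' Every subject's map is the shared template plus an individual deviation
#' field. Within a pair the deviation fields are correlated at the group's
#' target rho by mixing a shared-pair and a unique Gaussian component.
#' Polar-angle deviations are added on the angle with wrap-around, so that
#' the heritabilities of angle and eccentricity remain separately
#' controllable; eccentricity deviations are additive; pRF-size deviations
#' are multiplicative (log-normal) so sizes stay positive. Cartesian centres
#' \code{(x0, y0)} are recomputed from the perturbed (polar, ecc).
#'
#' Each subject also receives an individual region delineation, obtained by
#' jittering the template region boundaries with the same pair-correlated
#' construction, which makes the overlap analysis non-degenerate.
#'
#' @param surface A \code{prf_surface}.
#' @param template A \code{prf_map} from \code{\link{generate_template_map}}.
#' @param config A \code{\link{generator_config}}.
#' @return A \code{twin_cohort}: list with elements \code{surface},
#'   \code{subjects} (list of per-subject records), \code{n_mz}, \code{n_dz}
#'   and \code{config}.
#' @export
generate_twin_cohort <- function(surface, template, config = generator_config()) {
  if (!inherits(surface, "prf_surface")) stop_invalid("surface must be a prf_surface")
  if (nrow(template) != nrow(surface)) {
    stop_invalid("template and surface must have the same number of vertices")
  }
  nv <- nrow(surface)
  rb <- region_boundaries(surface)
  coords <- surface_coords(surface)
  maybe_seed(derive_seed(config$seed, "cohort"))

  smooth_dev <- function(d) {
    if (config$smoothing_fwhm > 0) {
      smooth_map(surface, d, config$smoothing_fwhm)
    } else d
  }

  subjects <- list()
  groups <- c(rep("MZ", config$n_mz), rep("DZ", config$n_dz))
  pair_num <- c(seq_len(config$n_mz), seq_len(config$n_dz))
  for (p in seq_along(groups)) {
    zyg <- groups[p]
    rho <- if (zyg == "MZ") config$rho_mz else config$rho_dz
    pair_id <- sprintf("%s%02d", zyg, pair_num[p])

    d_pol <- pair_deviations(nv, rho_for(rho, "polar"), sd_for(config$noise_sd, "polar"))
    d_ecc <- pair_deviations(nv, rho_for(rho, "ecc"), sd_for(config$noise_sd, "ecc"))
    d_sig <- pair_deviations(nv, rho_for(rho, "sigma"), sd_for(config$noise_sd, "sigma"))
    d_bnd <- pair_deviations(length(rb$bounds), rho_for(rho, "boundary"),
                             config$boundary_jitter_sd)

    for (tw in 1:2) {
      dev_p <- smooth_dev(if (tw == 1) d_pol$a else d_pol$b)
      dev_e <- smooth_dev(if (tw == 1) d_ecc$a else d_ecc$b)
      dev_s <- smooth_dev(if (tw == 1) d_sig$a else d_sig$b)
      polar_i <- wrap_angle(template$polar + dev_p)
      ecc_i <- template$ecc + dev_e  # may cross zero; centre flips through origin
      prf <- new_prf_map(x0 = ecc_i * cos(polar_i), y0 = ecc_i * sin(polar_i),
                         sigma = template$sigma * exp(dev_s),
                         amplitude = template$amplitude, r2 = template$r2)
      subjects[[length(subjects) + 1L]] <- list(
        subject_id = sprintf("%s_%d", pair_id, tw),
        pair_id = pair_id, zygosity = zyg,
        prf = prf,
        region_labels = jittered_labels(surface, rb,
                                        if (tw == 1) d_bnd$a else d_bnd$b),
        curvature = rep(NA_real_, nv),
        thickness = rep(NA_real_, nv),
        native_coord = coords,
        aligned_coord = coords)
    }
  }
  structure(list(surface = surface, subjects = subjects,
                 n_mz = config$n_mz, n_dz = config$n_dz, config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Twin cohort:", x$n_mz, "MZ pairs,", x$n_dz, "DZ pairs,",
      nrow(x$surface), "vertices\n")
  invisible(x)
}

#' Subject metadata table of a cohort
#'
#' @param cohort A \code{twin_cohort}.
#' @return Data frame with \code{subject_id}, \code{pair_id},
#'   \code{zygosity} and the subject's index in \code{cohort$subjects}.
#' @export
cohort_meta <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    pair_id = vapply(cohort$subjects, `[[`, "", "pair_id"),
    zygosity = vapply(cohort$subjects, `[[`, "", "zygosity"),
    index = seq_along(cohort$subjects),
    stringsAsFactors = FALSE)
}

#' Twin pairs of a cohort
#'
#' @param cohort A \code{twin_cohort}.
#' @param group Optional zygosity filter ("MZ" or "DZ").
#' @return Data frame with one row per pair: \code{pair_id},
#'   \code{zygosity}, subject indices \code{i} and \code{j}.
#' @export
cohort_pairs <- function(cohort, group = NULL) {
  meta <- cohort_meta(cohort)
  ids <- unique(meta$pair_id)
  out <- do.call(rbind, lapply(ids, function(pid) {
    rows <- meta[meta$pair_id == pid, ]
    if (nrow(rows) != 2L) stop_invalid("pair ", pid, " does not have two members")
    data.frame(pair_id = pid, zygosity = rows$zygosity[1],
               i = rows$index[1], j = rows$index[2], stringsAsFactors = FALSE)
  }))
  if (!is.null(group)) out <- out[out$zygosity == group, , drop = FALSE]
  out
}

subject_parameter <- function(subject, parameter) {
  switch(parameter,
         polar = subject$prf$polar,
         ecc = subject$prf$ecc,
         sigma = subject$prf$sigma,
         x0 = subject$prf$x0,
         y0 = subject$prf$y0,
         amplitude = subject$prf$amplitude,
         r2 = subject$prf$r2,
         curvature = subject$curvature,
         thickness = subject$thickness,
         stop_invalid("unknown parameter '", parameter, "'"))
}

#' Extract a subjects-by-vertices parameter matrix
#'
#' @param cohort A \code{twin_cohort}.
#' @param parameter One of "polar", "ecc", "sigma", "x0", "y0",
#'   "amplitude", "r2", "curvature", "thickness".
#' @param vertices Optional integer vector of vertex rows to keep.
#' @return Numeric matrix, one row per subject (rownames are subject ids).
#' @export
cohort_parameter_matrix <- function(cohort, parameter, vertices = NULL) {
  vals <- lapply(cohort$subjects, subject_parameter, parameter = parameter)
  m <- do.call(rbind, vals)
  rownames(m) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  if (!is.null(vertices)) m <- m[, vertices, drop = FALSE]
  m
}

#' Add pair-correlated cortical morphology maps to a cohort
#'
#' Curvature and thickness are built with the same shared/unique Gaussian
#' construction as the functional maps, on top of fixed mean patterns (a
#' sinusoidal folding ripple for curvature; a mean thickness of 2.5 mm with a
#' shallow gradient). Both are plain linear scalars, so deviations are
#' additive with no wrapping.
#'
#' @param cohort A \code{twin_cohort}.
#' @param config A \code{\link{generator_config}}; defaults to the cohort's.
#' @return The cohort with \code{curvature} and \code{thickness} filled in.
#' @export
generate_morphology_maps <- function(cohort, config = cohort$config) {
  surface <- cohort$surface
  nv <- nrow(surface)
  curv_t <- 0.3 * sin(2 * pi * surface$y / 10)
  thick_t <- 2.5 + 0.3 * sin(2 * pi * surface$x / 25)
  maybe_seed(derive_seed(config$seed, "morphology"))
  pairs <- cohort_pairs(cohort)
  for (p in seq_len(nrow(pairs))) {
    rho <- if (pairs$zygosity[p] == "MZ") config$rho_mz else config$rho_dz
    d_c <- pair_deviations(nv, rho_for(rho, "curvature"),
                           sd_for(config$noise_sd, "curvature"))
    d_t <- pair_deviations(nv, rho_for(rho, "thickness"),
                           sd_for(config$noise_sd, "thickness"))
    for (tw in 1:2) {
      idx <- if (tw == 1) pairs$i[p] else pairs$j[p]
      cohort$subjects[[idx]]$curvature <- curv_t + (if (tw == 1) d_c$a else d_c$b)
      cohort$subjects[[idx]]$thickness <- thick_t + (if (tw == 1) d_t$a else d_t$b)
    }
  }
  cohort
}

#' Simulate native-to-template alignment displacements
#'
#' Every subject's aligned coordinates are the shared template lattice; the
#' native coordinates are the aligned ones plus a random displacement field.
#' The per-subject overall displacement magnitude carries a configurable
#' twin coupling: with \code{pair_coupling = 0} the mean displacement
#' magnitudes of co-twins are uncorrelated, which is the negative control the
#' transformation-magnitude analysis expects.
#'
#' @param cohort A \code{twin_cohort}.
#' @param displacement_sd Per-axis SD in mm of the vertex displacements
#'   (default 1.5).
#' @param pair_coupling Correlation in [0, 1] of the co-twins' log
#'   displacement scales (default 0).
#' @param seed Integer seed.
#' @return The cohort with \code{native_coord} updated.
#' @export
generate_alignment_coordinates <- function(cohort, displacement_sd = 1.5,
                                           pair_coupling = 0, seed = 1L) {
  if (displacement_sd < 0) stop_invalid("displacement_sd must be >= 0")
  if (pair_coupling < 0 || pair_coupling > 1) {
    stop_invalid("pair_coupling must lie in [0, 1]")
  }
  maybe_seed(derive_seed(seed, "alignment"))
  nv <- nrow(cohort$surface)
  tau <- 0.3  # log-scale SD of the subject-level displacement magnitude
  pairs <- cohort_pairs(cohort)
  for (p in seq_len(nrow(pairs))) {
    z_pair <- stats::rnorm(1)
    for (tw in 1:2) {
      idx <- if (tw == 1) pairs$i[p] else pairs$j[p]
      z <- sqrt(pair_coupling) * z_pair +
        sqrt(1 - pair_coupling) * stats::rnorm(1)
      scale <- displacement_sd * exp(tau * z)
      disp <- matrix(stats::rnorm(nv * 2, 0, scale), nv, 2)
      if (displacement_sd == 0) disp[] <- 0
      cohort$subjects[[idx]]$native_coord <-
        cohort$subjects[[idx]]$aligned_coord + disp
    }
  }
  cohort
}
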