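#' Derive polar angle and eccentricity from pRF centres
#'
#' @param x0,y0 pRF centre coordinates in degrees of visual angle.
#' @return Data frame with columns \code{polar} (radians, in (-pi, pi]) and
#'   \code{ecc} (degrees, >= 0).
#' @export
prf_polar_ecc <- function(x0, y0) {
  data.frame(polar = atan2(y0, x0), ecc = sqrt(x0^2 + y0^2))
}

new_prf_map <- function(x0, y0, sigma, amplitude, r2) {
  pe <- prf_polar_ecc(x0, y0)
  m <- data.frame(x0 = x0, y0 = y0, sigma = sigma,
                  amplitude = amplitude, r2 = r2,
                  polar = pe$polar, ecc = pe$ecc)
  class(m) <- c("prf_map", "data.frame")
  m
}

#' Generate a template retinotopic map on a surface
#'
#' Produces the shared retinotopic organization that every simulated subject
#' inherits: eccentricity follows a smooth logarithmic gradient along the x
#' axis of the lattice (emulating the compressive cortical magnification of
#' eccentricity along the posterior-anterior axis), polar angle progresses
#' along the y axis, and pRF size grows linearly with eccentricity, as
#' observed throughout early visual cortex.
#'
#' @param surface A \code{prf_surface}.
#' @param ecc_range Length-2 numeric, minimum and maximum eccentricity in
#'   degrees (default \code{c(0.25, 8.5)}; 8.5 is the maximal stimulus
#'   eccentricity of the mapping stimulus).
#' @param sigma_intercept pRF size at 0 eccentricity, degrees (default 0.5).
#' @param sigma_slope Increase of pRF size per degree eccentricity
#'   (default 0.15).
#' @param amplitude Response amplitude assigned to every vertex (default 1).
#' @return A \code{prf_map} data frame with one row per surface vertex:
#'   \code{x0}, \code{y0}, \code{sigma}, \code{amplitude}, \code{r2} plus the
#'   derived \code{polar} and \code{ecc}.
#' @export
generate_template_map <- function(surface, ecc_range = c(0.25, 8.5),
                                  sigma_intercept = 0.5, sigma_slope = 0.15,
                                  amplitude = 1) {
  if (!inherits(surface, "prf_surface")) stop_invalid("surface must be a prf_surface")
  if (length(ecc_range) != 2L || any(ecc_range <= 0) || diff(ecc_range) <= 0) {
    stop_invalid("ecc_range must be increasing and positive")
  }
  if (sigma_intercept <= 0 || sigma_slope < 0) {
    stop_invalid("sigma_intercept must be > 0 and sigma_slope >= 0")
  }
  xn <- rescale01(surface$x)
  yn <- rescale01(surface$y)
  ecc <- exp(log(ecc_range[1]) + xn * (log(ecc_range[2]) - log(ecc_range[1])))
  # full cycle of polar angle across the sheet, wrapped into (-pi, pi]
  polar <- wrap_angle(-pi + yn * 2 * pi)
  sigma <- sigma_intercept + sigma_slope * ecc
  new_prf_map(x0 = ecc * cos(polar), y0 = ecc * sin(polar),
              sigma = sigma, amplitude = amplitude, r2 = rep(1, nrow(surface)))
}

rescale01 <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(rep(0.5, length(v)))
  (v - r[1]) / diff(r)
}
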