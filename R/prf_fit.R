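#' pRF model-fitting configuration
#'
#' Controls the coarse-to-fine scheme: an extensive grid search on spatially
#' smoothed data (correlation criterion), followed by a derivative-free
#' simplex refinement of \code{(x0, y0, sigma, amplitude)} on unsmoothed
#' data for vertices whose coarse goodness of fit exceeds the inclusion
#' threshold, and a final surface smoothing of the fitted parameter maps.
#'
#' @param x0_grid,y0_grid Grid positions in degrees
#'   (default \code{seq(-9, 9, by = 0.5)}).
#' @param sigma_grid pRF size grid in degrees
#'   (default \code{c(0.25, 0.5, 1, 2, 4, 8)}).
#' @param coarse_fwhm FWHM in mm of the smoothing applied to the data
#'   before the grid search (default 5; 0 disables smoothing).
#' @param final_fwhm FWHM in mm of the smoothing applied to the fitted
#'   parameter maps (default 3; 0 disables).
#' @param r2_threshold Coarse R-squared required for inclusion in the fine
#'   fit (default 0.05).
#' @param tol Relative tolerance of the simplex optimizer (default 1e-6).
#' @param maxit Maximum simplex iterations per vertex (default 500).
#' @return A \code{fit_config} list.
#' @export
fit_config <- function(x0_grid = seq(-9, 9, by = 0.5),
                       y0_grid = seq(-9, 9, by = 0.5),
                       sigma_grid = c(0.25, 0.5, 1, 2, 4, 8),
                       coarse_fwhm = 5, final_fwhm = 3,
                       r2_threshold = 0.05, tol = 1e-6, maxit = 500L) {
  if (length(x0_grid) < 1 || length(y0_grid) < 1 || length(sigma_grid) < 1) {
    stop_invalid("parameter grids must be non-empty")
  }
  if (any(sigma_grid <= 0)) stop_invalid("sigma grid must be positive")
  if (coarse_fwhm < 0 || final_fwhm < 0) stop_invalid("FWHM must be >= 0")
  if (r2_threshold < 0 || r2_threshold >= 1) {
    stop_invalid("r2_threshold must lie in [0, 1)")
  }
  structure(list(x0_grid = x0_grid, y0_grid = y0_grid,
                 sigma_grid = sigma_grid, coarse_fwhm = coarse_fwhm,
                 final_fwhm = final_fwhm, r2_threshold = r2_threshold,
                 tol = tol, maxit = as.integer(maxit)),
            class = "fit_config")
}

# Row-normalized Gaussian smoothing weights over surface vertices, truncated
# at 3 SD. Returns a dense matrix; surfaces used for fitting are modest.
smoothing_weights <- function(surface, fwhm, cutoff_sd = 3) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  xy <- surface_coords(surface)
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  w <- exp(-d2 / (2 * sd^2))
  w[d2 > (cutoff_sd * sd)^2] <- 0
  w / rowSums(w)
}

#' Smooth a per-vertex map on the surface
#'
#' Gaussian-weighted averaging over vertices within 3 SD of each vertex,
#' using the surface coordinates. Circular quantities are smoothed by
#' averaging unit vectors and taking the resulting direction, so wrap-around
#' is respected.
#'
#' @param surface A \code{prf_surface}.
#' @param values Numeric per-vertex vector.
#' @param fwhm Kernel FWHM in mm; 0 returns \code{values} unchanged.
#' @param circular Treat \code{values} as angles in radians (default FALSE).
#' @return Smoothed per-vertex vector.
#' @export
smooth_map <- function(surface, values, fwhm, circular = FALSE) {
  if (fwhm < 0) stop_invalid("fwhm must be >= 0")
  if (fwhm == 0) return(values)
  if (length(values) != nrow(surface)) {
    stop_invalid("values must have one entry per surface vertex")
  }
  w <- smoothing_weights(surface, fwhm)
  if (circular) {
    atan2(as.numeric(w %*% sin(values)), as.numeric(w %*% cos(values)))
  } else {
    as.numeric(w %*% values)
  }
}

#' Coarse grid-search pRF fit
#'
#' For every vertex, finds the grid combination of \code{(x0, y0, sigma)}
#' whose predicted time course has the maximal Pearson correlation with the
#' observed series, after smoothing the observed data on the surface with a
#' wide kernel. The squared correlation is stored as R-squared. Vertices
#' with a constant observed series get R-squared 0 and are flagged unfit.
#'
#' @param timecourses Time-by-vertex matrix of observed series.
#' @param surface A \code{prf_surface} with one row per column of
#'   \code{timecourses}.
#' @param apertures A \code{stim_apertures}.
#' @param config A \code{\link{fit_config}}.
#' @param hrf HRF kernel (default \code{canonical_hrf()}).
#' @return A \code{prf_map} with attributes \code{fitted} (logical per
#'   vertex) and \code{stage = "coarse"}.
#' @export
coarse_fit <- function(timecourses, surface, apertures,
                       config = fit_config(), hrf = canonical_hrf()) {
  timecourses <- as.matrix(timecourses)
  if (ncol(timecourses) != nrow(surface)) {
    stop_invalid("timecourses must have one column per surface vertex")
  }
  obs <- timecourses
  if (config$coarse_fwhm > 0) {
    obs <- obs %*% t(smoothing_weights(surface, config$coarse_fwhm))
  }
  grid <- as.matrix(expand.grid(x0 = config$x0_grid, y0 = config$y0_grid,
                                sigma = config$sigma_grid))
  preds <- predict_matrix(grid, apertures, hrf)
  pred_ok <- colSums(abs(preds)) > 0
  zobs <- znorm_cols(obs)
  obs_ok <- colSums(abs(zobs)) > 0
  r <- crossprod(zobs, preds) / (nrow(zobs) - 1)
  r[, !pred_ok] <- -Inf
  best <- max.col(r, ties.method = "first")
  r_best <- r[cbind(seq_len(nrow(r)), best)]
  r_best[!obs_ok] <- 0
  map <- new_prf_map(x0 = grid[best, 1], y0 = grid[best, 2],
                     sigma = grid[best, 3],
                     amplitude = rep(1, length(best)),
                     r2 = pmax(r_best, 0)^2)
  attr(map, "fitted") <- obs_ok
  attr(map, "stage") <- "coarse"
  map
}

#' Fine simplex pRF fit
#'
#' Refines \code{(x0, y0, sigma, amplitude)} per vertex with a Nelder-Mead
#' simplex seeded at the coarse solution, minimizing the sum of squared
#' residuals between the amplitude-scaled unit prediction and the
#' unsmoothed observed series. Only vertices whose coarse R-squared exceeds
#' the inclusion threshold are refined; the rest keep their coarse values
#' and are flagged. R-squared at this stage is \code{1 - SSres/SStot}.
#' Finally the fitted parameter maps are smoothed on the surface
#' (\code{final_fwhm}) and polar angle / eccentricity are re-derived.
#'
#' @inheritParams coarse_fit
#' @param coarse A coarse-stage \code{prf_map}.
#' @return A \code{prf_map} with attributes \code{fitted}, \code{refined}
#'   and \code{stage = "fine"}.
#' @export
fine_fit <- function(timecourses, coarse, surface, apertures,
                     config = fit_config(), hrf = canonical_hrf()) {
  timecourses <- as.matrix(timecourses)
  nv <- nrow(coarse)
  if (ncol(timecourses) != nv) {
    stop_invalid("timecourses do not match the coarse map")
  }
  fitted0 <- attr(coarse, "fitted")
  if (is.null(fitted0)) fitted0 <- rep(TRUE, nv)
  include <- fitted0 & coarse$r2 > config$r2_threshold

  frames <- apertures$frames
  n <- nrow(frames)
  l <- length(hrf)
  nfft <- stats::nextn(n + l - 1L, 2L)
  hfft <- stats::fft(c(hrf, rep(0, nfft - l)))
  xmat <- cbind(1, seq_len(n))
  proj <- xmat %*% solve(crossprod(xmat))
  pad <- rep(0, nfft - n)

  unit_pred <- function(p) {
    g <- exp(-((apertures$pix_x - p[1])^2 + (apertures$pix_y - p[2])^2) /
               (2 * p[3]^2))
    d <- as.numeric(frames %*% g)
    y <- Re(stats::fft(stats::fft(c(d, pad)) * hfft, inverse = TRUE))[seq_len(n)] / nfft
    dy <- y - as.numeric(proj %*% crossprod(xmat, y))
    s <- stats::sd(dy)
    if (is.na(s) || s <= 1e-10 * max(abs(y), .Machine$double.xmin)) {
      rep(0, n)
    } else {
      (dy - mean(dy)) / s
    }
  }

  out <- as.data.frame(coarse)
  refined <- rep(FALSE, nv)
  for (v in which(include)) {
    y <- timecourses[, v]
    sstot <- sum((y - mean(y))^2)
    if (sstot == 0) next
    p0 <- c(coarse$x0[v], coarse$y0[v], coarse$sigma[v])
    pu <- unit_pred(p0)
    a0 <- sum(pu * y) / max(sum(pu * pu), .Machine$double.eps)
    objective <- function(par) {
      if (par[3] <= 1e-3) return(1e10)
      sum((y - par[4] * unit_pred(par[1:3]))^2)
    }
    fit <- stats::optim(c(p0, a0), objective, method = "Nelder-Mead",
                        control = list(reltol = config$tol,
                                       maxit = config$maxit))
    out$x0[v] <- fit$par[1]
    out$y0[v] <- fit$par[2]
    out$sigma[v] <- fit$par[3]
    out$amplitude[v] <- fit$par[4]
    out$r2[v] <- 1 - fit$value / sstot
    refined[v] <- TRUE
  }
  if (config$final_fwhm > 0) {
    for (col in c("x0", "y0", "sigma", "amplitude")) {
      out[[col]] <- smooth_map(surface, out[[col]], config$final_fwhm)
    }
  }
  map <- new_prf_map(out$x0, out$y0, out$sigma, out$amplitude, out$r2)
  attr(map, "fitted") <- fitted0
  attr(map, "refined") <- refined
  attr(map, "stage") <- "fine"
  map
}

#' Visual field coverage of a region
#'
#' Pointwise mean over region vertices of unit-height Gaussian pRF profiles
#' evaluated on a visual-field grid; values lie in [0, 1].
#'
#' @param prf_map A \code{prf_map}.
#' @param vertices Integer vector of map rows to include (default: all).
#' @param xlim Field extent in degrees (default \code{c(-9, 9)}).
#' @param n Grid points per side (default 61).
#' @return A \code{vf_coverage} list with \code{x}, \code{y} and the
#'   \code{coverage} matrix (rows index \code{x}).
#' @export
visual_field_coverage <- function(prf_map, vertices = NULL,
                                  xlim = c(-9, 9), n = 61L) {
  if (is.null(vertices)) vertices <- seq_len(nrow(prf_map))
  if (length(vertices) == 0L) stop_invalid("empty vertex set")
  gx <- seq(xlim[1], xlim[2], length.out = n)
  grid <- expand.grid(x = gx, y = gx)
  acc <- rep(0, nrow(grid))
  for (start in seq(1L, length(vertices), by = 256L)) {
    idx <- vertices[start:min(start + 255L, length(vertices))]
    g <- gaussian_profiles(cbind(prf_map$x0[idx], prf_map$y0[idx],
                                 prf_map$sigma[idx]), grid$x, grid$y)
    acc <- acc + rowSums(g)
  }
  structure(list(x = gx, y = gx,
                 coverage = matrix(acc / length(vertices), n, n)),
            class = "vf_coverage")
}

#' Mean pRF size per eccentricity band
#'
#' Bins vertices into eccentricity bands of fixed width and reports the mean
#' pRF size per band; empty bands are omitted.
#'
#' @param prf_map A \code{prf_map}.
#' @param vertices Integer vector of map rows to include (default: all).
#' @param band_width Band width in degrees (default 1).
#' @return Data frame with \code{band_lo}, \code{band_hi},
#'   \code{band_center}, \code{n} and \code{mean_sigma}.
#' @export
prf_size_by_eccentricity <- function(prf_map, vertices = NULL, band_width = 1) {
  if (band_width <= 0) stop_invalid("band_width must be > 0")
  if (is.null(vertices)) vertices <- seq_len(nrow(prf_map))
  ecc <- prf_map$ecc[vertices]
  sig <- prf_map$sigma[vertices]
  band <- floor(ecc / band_width)
  agg <- stats::aggregate(sig, by = list(band = band), FUN = mean)
  cnt <- as.integer(table(band))
  data.frame(band_lo = agg$band * band_width,
             band_hi = (agg$band + 1) * band_width,
             band_center = (agg$band + 0.5) * band_width,
             n = cnt, mean_sigma = agg$x)
}
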