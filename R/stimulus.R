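#' Configuration of the wedge-and-ring mapping stimulus
#'
#' Defaults reproduce the mapping run geometry: a 12 deg wide wedge rotating
#' in 60 one-second steps (6 cycles per run), a ring expanding/contracting
#' over 36 logarithmic steps up to 8.5 deg eccentricity (10 cycles per run),
#' and a 30 s fixation-only block after every quarter of the run, for 480
#' frames in total (490 acquired volumes minus 10 dummies at 1 s per frame).
#'
#' @param wedge_width_deg Angular width of the wedge, degrees (default 12).
#' @param wedge_steps Rotation steps per wedge cycle (default 60).
#' @param wedge_cycles Wedge cycles per run (default 6).
#' @param ring_max_ecc Maximal ring eccentricity, degrees (default 8.5).
#' @param ring_min_ecc Innermost ring radius, degrees (default 0.5).
#' @param ring_steps Logarithmic radius steps per ring cycle (default 36).
#' @param ring_cycles Ring cycles per run (default 10).
#' @param fixation_s Duration of each fixation-only block, seconds (default 30).
#' @param n_blocks Number of stimulation quarters (default 4).
#' @param frame_s Frame (volume) duration in seconds (default 1).
#' @param fov Half-width of the modelled visual field, degrees (default 9).
#' @param resolution Pixels per side of the square aperture grid (default 101).
#' @return A \code{stim_config} list.
#' @export
stim_config <- function(wedge_width_deg = 12, wedge_steps = 60L,
                        wedge_cycles = 6L, ring_max_ecc = 8.5,
                        ring_min_ecc = 0.5, ring_steps = 36L,
                        ring_cycles = 10L, fixation_s = 30L, n_blocks = 4L,
                        frame_s = 1, fov = 9, resolution = 101L) {
  if (fov <= 0 || resolution < 3) stop_invalid("fov and resolution must be positive")
  if (ring_min_ecc <= 0 || ring_max_ecc <= ring_min_ecc) {
    stop_invalid("need 0 < ring_min_ecc < ring_max_ecc")
  }
  n_wedge <- wedge_steps * wedge_cycles
  n_ring <- ring_steps * ring_cycles
  if (n_wedge != n_ring) {
    stop_invalid("wedge and ring cycle counts must span the same number of ",
                 "stimulation frames (got ", n_wedge, " vs ", n_ring, ")")
  }
  if (n_wedge %% n_blocks != 0) {
    stop_invalid("stimulation frames (", n_wedge,
                 ") not divisible into ", n_blocks, " blocks")
  }
  structure(list(wedge_width_deg = wedge_width_deg, wedge_steps = wedge_steps,
                 wedge_cycles = wedge_cycles, ring_max_ecc = ring_max_ecc,
                 ring_min_ecc = ring_min_ecc, ring_steps = ring_steps,
                 ring_cycles = ring_cycles, fixation_s = fixation_s,
                 n_blocks = n_blocks, frame_s = frame_s, fov = fov,
                 resolution = as.integer(resolution)),
            class = "stim_config")
}

#' Build binary aperture frames for the wedge-and-ring stimulus
#'
#' Each frame is the union of the rotating wedge and the expanding or
#' contracting ring annulus on a square pixel grid in degrees of visual
#' angle; frames inside the fixation blocks are all-zero. The run is laid
#' out as \code{n_blocks} stimulation quarters, each followed by one
#' fixation block, with wedge and ring phase continuing across quarters.
#'
#' @param config A \code{\link{stim_config}}.
#' @param wedge,ring Include the wedge / ring component (both TRUE by
#'   default; disabling one yields a single-component stimulus for
#'   simulation experiments).
#' @return A \code{stim_apertures} list: \code{frames} (time-by-pixel 0/1
#'   matrix), pixel coordinates \code{pix_x}, \code{pix_y} (degrees),
#'   \code{frame_s}, per-frame metadata (\code{wedge_angle} in radians and
#'   \code{ring_step}, NA during fixation), the ring \code{radii} grid and
#'   the \code{config}.
#' @export
build_apertures <- function(config = stim_config(), wedge = TRUE, ring = TRUE) {
  if (!wedge && !ring) stop_invalid("at least one stimulus component needed")
  px <- seq(-config$fov, config$fov, length.out = config$resolution)
  grid <- expand.grid(x = px, y = px)
  pe <- prf_polar_ecc(grid$x, grid$y)

  n_stim <- config$wedge_steps * config$wedge_cycles
  per_block <- n_stim %/% config$n_blocks
  fix_frames <- as.integer(config$fixation_s / config$frame_s)
  n_total <- n_stim + config$n_blocks * fix_frames

  radii <- exp(seq(log(config$ring_min_ecc), log(config$ring_max_ecc),
                   length.out = config$ring_steps + 1L))
  half_w <- config$wedge_width_deg * pi / 360  # half width in radians

  frames <- matrix(0, n_total, nrow(grid))
  wedge_angle <- rep(NA_real_, n_total)
  ring_step <- rep(NA_integer_, n_total)
  t_out <- 0L
  for (b in seq_len(config$n_blocks)) {
    for (s in seq_len(per_block)) {
      stim_idx <- (b - 1L) * per_block + s - 1L  # 0-based stimulation frame
      t_out <- t_out + 1L
      ang <- 2 * pi * (stim_idx %% config$wedge_steps) / config$wedge_steps
      k <- stim_idx %% config$ring_steps
      wedge_angle[t_out] <- ang
      ring_step[t_out] <- k
      mask <- rep(FALSE, nrow(grid))
      if (wedge) {
        mask <- mask | (abs(wrap_angle(pe$polar - ang)) <= half_w &
                          pe$ecc <= config$ring_max_ecc)
      }
      if (ring) {
        mask <- mask | (pe$ecc >= radii[k + 1L] & pe$ecc < radii[k + 2L])
      }
      frames[t_out, ] <- as.numeric(mask)
    }
    t_out <- t_out + fix_frames  # fixation block stays all-zero
  }
  structure(list(frames = frames, pix_x = grid$x, pix_y = grid$y,
                 frame_s = config$frame_s, wedge_angle = wedge_angle,
                 ring_step = ring_step, radii = radii, config = config),
            class = "stim_apertures")
}

#' @export
print.stim_apertures <- function(x, ...) {
  cat("Aperture sequence:", nrow(x$frames), "frames,",
      length(x$pix_x), "pixels,", sum(rowSums(x$frames) == 0),
      "fixation frames\n")
  invisible(x)
}

#' Double-gamma HRF parameters
#'
#' Conventional canonical settings: response peak at 6 s, undershoot at
#' 16 s, unit dispersions, undershoot one sixth of the peak.
#'
#' @param peak_delay,peak_disp Delay (s) and dispersion of the response gamma.
#' @param under_delay,under_disp Delay (s) and dispersion of the undershoot.
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return An \code{hrf_params} list.
#' @export
hrf_params <- function(peak_delay = 6, peak_disp = 1,
                       under_delay = 16, under_disp = 1, ratio = 6) {
  if (peak_delay <= 0 || under_delay <= 0 || peak_disp <= 0 || under_disp <= 0) {
    stop_invalid("HRF delays and dispersions must be > 0")
  }
  if (ratio <= 0) stop_invalid("HRF ratio must be > 0")
  structure(list(peak_delay = peak_delay, peak_disp = peak_disp,
                 under_delay = under_delay, under_disp = under_disp,
                 ratio = ratio), class = "hrf_params")
}

#' Sample a canonical double-gamma HRF kernel
#'
#' @param params An \code{\link{hrf_params}}.
#' @param dt Sampling interval in seconds (default 1).
#' @param duration Kernel length in seconds (default 32).
#' @return Numeric kernel sampled at \code{seq(0, duration, by = dt)},
#'   scaled to unit peak.
#' @export
canonical_hrf <- function(params = hrf_params(), dt = 1, duration = 32) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (duration <= 0) stop_invalid("duration must be > 0")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_disp,
                     scale = params$peak_disp) -
    stats::dgamma(t, shape = params$under_delay / params$under_disp,
                  scale = params$under_disp) / params$ratio
  h / max(h)
}

# Causal convolution of each column of `m` with kernel `h`, truncated to the
# original length (FFT-based; used for predicted neural drive -> BOLD).
convolve_cols <- function(m, h) {
  n <- nrow(m)
  l <- length(h)
  nfft <- stats::nextn(n + l - 1L, 2L)
  hp <- c(h, rep(0, nfft - l))
  mp <- rbind(m, matrix(0, nfft - n, ncol(m)))
  out <- Re(stats::mvfft(stats::mvfft(mp) * stats::fft(hp), inverse = TRUE)) / nfft
  out[seq_len(n), , drop = FALSE]
}

# Neural drive of a set of Gaussian pRFs: apertures (T x P) times Gaussian
# profiles (P x K). `pars` is a matrix with columns x0, y0, sigma.
prf_drive <- function(pars, apertures) {
  g <- gaussian_profiles(pars, apertures$pix_x, apertures$pix_y)
  apertures$frames %*% g
}

gaussian_profiles <- function(pars, pix_x, pix_y) {
  pars <- matrix(as.numeric(pars), ncol = 3)
  dx2 <- outer(pix_x, pars[, 1], "-")^2
  dy2 <- outer(pix_y, pars[, 2], "-")^2
  exp(-(dx2 + dy2) / (2 * rep(pars[, 3]^2, each = length(pix_x))))
}

#' Predict a pRF mapping time course
#'
#' The neural drive at each frame is the summed Gaussian pRF profile over the
#' stimulated pixels; the drive is convolved with the HRF, scaled by the
#' amplitude, then (by default) linearly detrended and z-normalized to match
#' the preprocessing applied to measured time courses. An all-constant series
#' z-normalizes to all zeros.
#'
#' @param prf Numeric vector or list with \code{x0}, \code{y0}, \code{sigma}
#'   and optionally \code{amplitude} (default 1).
#' @param apertures A \code{stim_apertures}.
#' @param hrf HRF kernel sampled at the frame rate
#'   (default \code{canonical_hrf()}).
#' @param detrend,normalize Apply linear detrending / z-normalization
#'   (defaults TRUE).
#' @return Numeric time course, one value per frame.
#' @export
predict_timecourse <- function(prf, apertures, hrf = canonical_hrf(),
                               detrend = TRUE, normalize = TRUE) {
  prf <- as.list(prf)
  if (is.null(prf$amplitude)) prf$amplitude <- 1
  if (prf$sigma <= 0) stop_invalid("sigma must be > 0")
  d <- prf_drive(cbind(prf$x0, prf$y0, prf$sigma), apertures)
  y <- prf$amplitude * convolve_cols(d, hrf)
  mag <- apply(abs(y), 2L, max)
  if (detrend) y <- detrend_cols(y)
  if (normalize) y <- znorm_cols(y, ref_mag = mag)
  as.numeric(y)
}

# Batch forward model for fitting: parameter matrix (K x 3) -> T x K matrix
# of detrended, z-normalized predictions; chunked to bound memory.
predict_matrix <- function(pars, apertures, hrf, chunk = 512L) {
  pars <- as.matrix(pars)
  k <- nrow(pars)
  n <- nrow(apertures$frames)
  out <- matrix(0, n, k)
  for (start in seq(1L, k, by = chunk)) {
    idx <- start:min(start + chunk - 1L, k)
    y <- convolve_cols(prf_drive(pars[idx, , drop = FALSE], apertures), hrf)
    out[, idx] <- znorm_cols(detrend_cols(y), ref_mag = apply(abs(y), 2L, max))
  }
  out
}
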