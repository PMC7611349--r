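#' Wrap angles into (-pi, pi]
#'
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(theta) {
  w <- theta %% (2 * pi)
  big <- !is.na(w) & w > pi
  w[big] <- w[big] - 2 * pi
  w
}

#' Circular mean of angles
#'
#' @param theta Numeric vector of angles in radians.
#' @return The direction of the mean resultant vector, in (-pi, pi].
#' @export
circ_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

# Deterministic substream seed derived from a master seed and a stage label.
# Keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973 + 17) %% 2147483629)
}

# set.seed() only when a seed is supplied; NULL continues the caller's stream
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Column-wise z-scoring that maps (numerically) constant columns to all-zero
# columns — the contract used for predicted and observed fMRI time courses.
# Constancy is judged relative to the column's magnitude so that detrending
# residue of order eps * |signal| is not blown up to unit variance.
znorm_cols <- function(m, ref_mag = NULL) {
  m <- as.matrix(m)
  mag <- if (is.null(ref_mag)) apply(abs(m), 2L, max) else ref_mag
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu)
  sd <- sqrt(colSums(m^2) / (nrow(m) - 1))
  keep <- sd > 1e-10 * pmax(mag, .Machine$double.xmin)
  m[, keep] <- sweep(m[, keep, drop = FALSE], 2L, sd[keep], "/")
  m[, !keep] <- 0
  m
}

# Remove a linear trend (intercept + slope in time) from each column.
detrend_cols <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  x <- cbind(1, seq_len(n))
  m - x %*% solve(crossprod(x), crossprod(x, m))
}
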