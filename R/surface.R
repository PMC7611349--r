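#' Build a lattice surface model with labelled visual regions
#'
#' Constructs the spatial substrate on which all maps live: a regular 2-D
#' lattice of vertices in a common coordinate frame, partitioned into
#' contiguous blocks labelled \code{V1}, \code{V2}, \code{V3} (or any supplied
#' names). Real cortical meshes can be substituted anywhere downstream because
#' every spatial operator in the package only uses vertex coordinates and
#' distances.
#'
#' The default region sizes decrease along the visual hierarchy, with V3 the
#' smallest region at 3409 vertices.
#'
#' @param n_vertices_per_region Named integer vector of vertex counts, one per
#'   region, e.g. \code{c(V1 = 5500, V2 = 4400, V3 = 3409)}.
#' @param spacing Lattice spacing in mm (default 1).
#' @param jitter Optional uniform coordinate jitter amplitude in mm
#'   (default 0, i.e. a perfectly regular lattice).
#' @param seed Integer seed used only when \code{jitter > 0}.
#' @return A \code{prf_surface}: a data frame with columns \code{vertex_id}
#'   (0-based, contiguous), \code{x}, \code{y} (mm) and \code{region}.
#' @examples
#' surf <- build_surface(c(V1 = 4, V2 = 4, V3 = 4))
#' table(surf$region)
#' @export
build_surface <- function(n_vertices_per_region = c(V1 = 5500L, V2 = 4400L, V3 = 3409L),
                          spacing = 1, jitter = 0, seed = 1L) {
  n <- n_vertices_per_region
  if (is.null(names(n)) || any(!nzchar(names(n)))) {
    stop_invalid("n_vertices_per_region must be a named vector of region sizes")
  }
  if (any(n < 1) || any(n != round(n))) {
    stop_invalid("region vertex counts must be positive integers")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop_invalid("spacing must be a single positive number")
  }
  if (jitter < 0) stop_invalid("jitter must be >= 0")

  rows_used <- 0L
  pieces <- vector("list", length(n))
  for (k in seq_along(n)) {
    nk <- as.integer(n[k])
    width <- ceiling(sqrt(nk))
    idx <- seq_len(nk) - 1L
    col <- idx %% width
    row <- idx %/% width
    pieces[[k]] <- data.frame(
      x = col * spacing,
      y = (rows_used + row) * spacing,
      region = names(n)[k],
      stringsAsFactors = FALSE
    )
    rows_used <- rows_used + max(row) + 1L
  }
  surf <- do.call(rbind, pieces)
  surf <- data.frame(vertex_id = seq_len(nrow(surf)) - 1L, surf,
                     stringsAsFactors = FALSE)
  if (jitter > 0) {
    maybe_seed(seed)
    surf$x <- surf$x + stats::runif(nrow(surf), -jitter, jitter)
    surf$y <- surf$y + stats::runif(nrow(surf), -jitter, jitter)
  }
  attr(surf, "spacing") <- spacing
  class(surf) <- c("prf_surface", "data.frame")
  surf
}

#' @export
print.prf_surface <- function(x, ...) {
  cat("Surface model:", nrow(x), "vertices,",
      "regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                as.integer(table(x$region))), collapse = ", "),
      "\n")
  invisible(x)
}

surface_coords <- function(surface) {
  as.matrix(surface[, c("x", "y")])
}

region_vertices <- function(surface, region) {
  v <- which(surface$region == region)
  if (length(v) == 0L) stop_invalid("region '", region, "' is empty")
  v
}

#' Subsample vertices with a minimum spatial separation
#'
#' Greedy selection used for the spatial non-adjacency control: vertices of a
#' region are visited in a seeded random order and kept only if they lie at
#' least \code{min_dist} mm from every vertex already kept. The result is a
#' subset whose pairwise distances are all at least \code{min_dist}, breaking
#' the spatial autocorrelation between neighbouring data points.
#'
#' @param surface A \code{prf_surface}.
#' @param region Region label to subsample.
#' @param min_dist Minimum pairwise separation in mm (default 8).
#' @param seed Integer seed controlling the visiting order.
#' @return Integer vector of row indices into \code{surface}.
#' @export
subsample_vertices <- function(surface, region, min_dist = 8, seed = 1L) {
  if (min_dist <= 0) stop_invalid("min_dist must be > 0")
  verts <- region_vertices(surface, region)
  xy <- surface_coords(surface)[verts, , drop = FALSE]
  maybe_seed(seed)
  ord <- sample.int(length(verts))
  keep <- integer(0)
  kx <- numeric(0)
  ky <- numeric(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all((kx - xy[i, 1])^2 + (ky - xy[i, 2])^2 >= min_dist^2)) {
      keep <- c(keep, i)
      kx <- c(kx, xy[i, 1])
      ky <- c(ky, xy[i, 2])
    }
  }
  sort(verts[keep])
}
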