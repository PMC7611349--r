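#' Write a twin cohort to disk
#'
#' One vertex table per subject (CSV: vertex_id, region label of that
#' subject's delineation, pRF parameters, morphology and native/aligned
#' coordinates) plus a surface table and a JSON manifest listing pair
#' membership, zygosity and file paths.
#'
#' @param cohort A \code{twin_cohort}.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surf_file <- "surface.csv"
  utils::write.csv(as.data.frame(cohort$surface),
                   file.path(dir, surf_file), row.names = FALSE)
  meta <- cohort_meta(cohort)
  files <- character(nrow(meta))
  for (k in seq_len(nrow(meta))) {
    s <- cohort$subjects[[k]]
    tab <- data.frame(
      vertex_id = cohort$surface$vertex_id,
      region = s$region_labels,
      x0 = s$prf$x0, y0 = s$prf$y0, sigma = s$prf$sigma,
      amplitude = s$prf$amplitude, r2 = s$prf$r2,
      curvature = s$curvature, thickness = s$thickness,
      native_x = s$native_coord[, 1], native_y = s$native_coord[, 2],
      aligned_x = s$aligned_coord[, 1], aligned_y = s$aligned_coord[, 2])
    files[k] <- sprintf("sub-%s.csv", s$subject_id)
    utils::write.csv(tab, file.path(dir, files[k]), row.names = FALSE)
  }
  manifest <- list(format_version = "1.0",
                   n_mz = cohort$n_mz, n_dz = cohort$n_dz,
                   surface_file = surf_file,
                   subjects = data.frame(subject_id = meta$subject_id,
                                         pair_id = meta$pair_id,
                                         zygosity = meta$zygosity,
                                         file = files,
                                         stringsAsFactors = FALSE))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a twin cohort from a manifest
#'
#' Validates the cohort on load: every subject file must exist, map lengths
#' must match the surface, each pair must have exactly two members of equal
#' zygosity, and pRF size must be positive wherever variance explained is
#' positive.
#'
#' @param manifest_path Path to a \code{manifest.json} written by
#'   \code{\link{write_cohort}}.
#' @return A \code{twin_cohort}.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_invalid("manifest not found: ", manifest_path)
  }
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  need <- c("n_mz", "n_dz", "surface_file", "subjects")
  if (!all(need %in% names(man))) {
    stop_invalid("manifest is missing fields: ",
                 paste(setdiff(need, names(man)), collapse = ", "))
  }
  surf <- utils::read.csv(file.path(dir, man$surface_file),
                          stringsAsFactors = FALSE)
  if (any(surf$vertex_id != seq_len(nrow(surf)) - 1L)) {
    stop_invalid("surface vertex ids must be contiguous from 0")
  }
  attr(surf, "spacing") <- NA_real_
  class(surf) <- c("prf_surface", "data.frame")

  subs <- man$subjects
  counts <- table(subs$pair_id)
  if (any(counts != 2)) {
    stop_invalid("pairs without exactly two members: ",
                 paste(names(counts)[counts != 2], collapse = ", "))
  }
  for (pid in unique(subs$pair_id)) {
    z <- subs$zygosity[subs$pair_id == pid]
    if (length(unique(z)) != 1) {
      stop_invalid("pair ", pid, " mixes zygosities")
    }
  }
  subjects <- lapply(seq_len(nrow(subs)), function(k) {
    f <- file.path(dir, subs$file[k])
    if (!file.exists(f)) stop_invalid("subject file missing: ", subs$file[k])
    tab <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (nrow(tab) != nrow(surf)) {
      stop_invalid("subject ", subs$subject_id[k],
                   " has ", nrow(tab), " vertices; surface has ", nrow(surf))
    }
    bad <- !is.na(tab$r2) & tab$r2 > 0 & !is.na(tab$sigma) & tab$sigma <= 0
    if (any(bad)) {
      stop_invalid("subject ", subs$subject_id[k],
                   ": sigma <= 0 at vertices with r2 > 0")
    }
    list(subject_id = subs$subject_id[k], pair_id = subs$pair_id[k],
         zygosity = subs$zygosity[k],
         prf = new_prf_map(tab$x0, tab$y0, tab$sigma, tab$amplitude, tab$r2),
         region_labels = tab$region,
         curvature = tab$curvature, thickness = tab$thickness,
         native_coord = cbind(x = tab$native_x, y = tab$native_y),
         aligned_coord = cbind(x = tab$aligned_x, y = tab$aligned_y))
  })
  structure(list(surface = surf, subjects = subjects,
                 n_mz = as.integer(man$n_mz), n_dz = as.integer(man$n_dz),
                 config = NULL),
            class = "twin_cohort")
}
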