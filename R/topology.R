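#' Jaccard overlap of two vertex sets
#'
#' The area of overlap divided by the area of union: 1 when the two sets are
#' identical and non-empty, 0 when they are disjoint.
#'
#' @param a,b Vectors of vertex identifiers (treated as sets).
#' @return The Jaccard coefficient in [0, 1].
#' @examples
#' jaccard_overlap(1:4, 3:6)  # 2/6
#' @export
jaccard_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop_invalid("Jaccard overlap is undefined for two empty sets")
  }
  length(intersect(a, b)) / length(union(a, b))
}

subject_region_set <- function(subject, region) {
  which(subject$region_labels == region)
}

#' Per-pair regional overlap scores for a cohort
#'
#' @param cohort A \code{twin_cohort} whose subjects carry individual
#'   region delineations.
#' @param regions Region labels to score (default \code{c("V1","V2","V3")}).
#' @return Data frame with \code{pair_id}, \code{zygosity}, \code{region},
#'   \code{jaccard}.
#' @export
region_overlap_scores <- function(cohort, regions = c("V1", "V2", "V3")) {
  pairs <- cohort_pairs(cohort)
  out <- expand.grid(pair_id = pairs$pair_id, region = regions,
                     stringsAsFactors = FALSE)
  out$zygosity <- pairs$zygosity[match(out$pair_id, pairs$pair_id)]
  out$jaccard <- mapply(function(pid, reg) {
    row <- pairs[pairs$pair_id == pid, ]
    jaccard_overlap(subject_region_set(cohort$subjects[[row$i]], reg),
                    subject_region_set(cohort$subjects[[row$j]], reg))
  }, out$pair_id, out$region)
  out[, c("pair_id", "zygosity", "region", "jaccard")]
}

#' Multivariate map similarity between two pRF maps
#'
#' For each vertex, the Euclidean distance between the twins' pRFs in the
#' three-dimensional space of x-position, y-position and pRF size; distances
#' are averaged over the region and inverted to give a similarity score.
#' Inference downstream uses the logarithm of the score
#' (\code{log_similarity = -log(mean_distance)}) to ensure linearity. An
#' exactly zero mean distance (identical maps) is an error rather than an
#' infinite score.
#'
#' @param prf_a,prf_b \code{prf_map}s of the two twins.
#' @param vertices Integer vector of map rows defining the region.
#' @return List with \code{mean_distance}, \code{similarity},
#'   \code{log_similarity}.
#' @export
map_similarity <- function(prf_a, prf_b, vertices) {
  if (length(vertices) == 0L) stop_invalid("region is empty")
  d <- sqrt((prf_a$x0[vertices] - prf_b$x0[vertices])^2 +
              (prf_a$y0[vertices] - prf_b$y0[vertices])^2 +
              (prf_a$sigma[vertices] - prf_b$sigma[vertices])^2)
  md <- mean(d)
  if (md == 0) {
    stop_invalid("maps are identical over the region; similarity undefined")
  }
  list(mean_distance = md, similarity = 1 / md, log_similarity = -log(md))
}

#' Per-pair map-similarity scores for a cohort
#'
#' @inheritParams region_overlap_scores
#' @return Data frame with \code{pair_id}, \code{zygosity}, \code{region},
#'   \code{mean_distance}, \code{similarity}, \code{log_similarity}.
#' @export
map_similarity_scores <- function(cohort, regions = c("V1", "V2", "V3")) {
  pairs <- cohort_pairs(cohort)
  rows <- list()
  for (reg in regions) {
    verts <- region_vertices(cohort$surface, reg)
    for (p in seq_len(nrow(pairs))) {
      s <- map_similarity(cohort$subjects[[pairs$i[p]]]$prf,
                          cohort$subjects[[pairs$j[p]]]$prf, verts)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[p], zygosity = pairs$zygosity[p],
        region = reg, mean_distance = s$mean_distance,
        similarity = s$similarity, log_similarity = s$log_similarity,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-way fixed-effects ANOVA on pair-level scores
#'
#' Standard two-way ANOVA with interaction of zygosity and region on
#' pair-level scores (each pair contributes one score per region). For
#' similarity scores, pass the log scores.
#'
#' @param scores Data frame with columns \code{value}, \code{zygosity},
#'   \code{region}.
#' @return Data frame with one row per term: \code{term}, \code{df},
#'   \code{sumsq}, \code{meansq}, \code{F}, \code{p}.
#' @export
two_way_anova <- function(scores) {
  need <- c("value", "zygosity", "region")
  if (!all(need %in% names(scores))) {
    stop_invalid("scores must have columns value, zygosity, region")
  }
  if (length(unique(scores$zygosity)) < 2 || length(unique(scores$region)) < 2) {
    stop_invalid("both factors need at least two levels")
  }
  if (any(!is.finite(scores$value))) stop_invalid("scores must be finite")
  tab <- table(scores$zygosity, scores$region)
  if (any(tab < 1)) stop_invalid("every zygosity-by-region cell needs data")
  fit <- stats::lm(value ~ zygosity * region, data = scores)
  a <- suppressWarnings(stats::anova(fit))
  out <- data.frame(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
                    meansq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  # degenerate limits: zero between-group variance -> F = 0; a noiseless
  # effect (zero residual variance) -> large finite F with p ~ 0
  n_terms <- nrow(out) - 1L
  if (stats::var(scores$value) == 0) {
    out$F[seq_len(n_terms)] <- 0
    out$p[seq_len(n_terms)] <- 1
  }
  zero_term <- is.nan(out$F) & out$sumsq < .Machine$double.eps
  out$F[zero_term] <- 0
  out$p[zero_term] <- 1
  inf_term <- !is.na(out$F) & is.infinite(out$F)
  out$F[inf_term] <- .Machine$double.xmax^0.5
  out$p[inf_term] <- 0
  out
}

# Random re-pairing of subjects within a group, avoiding every true pair.
pseudo_pairing <- function(n_subjects, true_pairs, max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    ord <- sample.int(n_subjects)
    prop <- matrix(ord, ncol = 2, byrow = TRUE)
    key <- paste(pmin(prop[, 1], prop[, 2]), pmax(prop[, 1], prop[, 2]))
    if (!any(key %in% true_pairs)) return(prop)
  }
  prop  # extremely unlikely fallback; keep last proposal
}

#' Permutation test of within-pair regional overlap
#'
#' Shuffles the participants of one zygosity group into pseudo-random pairs
#' \code{n_perm} times (never re-creating a true pair), recomputes the mean
#' Jaccard overlap of the pseudo-pairs, and reports the proportion of
#' permutations whose mean overlap is greater than or equal to the overlap
#' observed in the true twin pairs.
#'
#' @param cohort A \code{twin_cohort}.
#' @param region Region label.
#' @param group Zygosity group, "MZ" or "DZ".
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param smoothed If TRUE, report the add-one smoothed p-value
#'   \code{(b + 1) / (n_perm + 1)} instead of the plain proportion.
#' @return List with \code{p}, \code{observed}, \code{perm} (the null
#'   distribution of mean overlaps).
#' @export
permutation_overlap_test <- function(cohort, region, group, n_perm = 1000L,
                                     seed = 1L, smoothed = FALSE) {
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  pairs <- cohort_pairs(cohort, group)
  if (nrow(pairs) < 3) stop_invalid("need at least 3 pairs in the group")
  subj_idx <- c(rbind(pairs$i, pairs$j))
  m <- length(subj_idx)
  sets <- lapply(subj_idx, function(i) {
    subject_region_set(cohort$subjects[[i]], region)
  })
  jmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      jmat[i, j] <- jmat[j, i] <- jaccard_overlap(sets[[i]], sets[[j]])
    }
  }
  true_local <- matrix(seq_len(m), ncol = 2, byrow = TRUE)
  observed <- mean(jmat[true_local])
  true_key <- paste(true_local[, 1], true_local[, 2])
  maybe_seed(derive_seed(seed, paste("overlap", region, group)))
  perm <- vapply(seq_len(n_perm), function(k) {
    mean(jmat[pseudo_pairing(m, true_key)])
  }, numeric(1))
  b <- sum(perm >= observed)
  p <- if (smoothed) (b + 1) / (n_perm + 1) else b / n_perm
  list(p = p, observed = observed, perm = perm)
}
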