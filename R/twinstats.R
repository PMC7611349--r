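#' Remove the sample-mean pattern from per-subject maps
#'
#' Subtracts the vertex-wise mean pattern of the whole participant sample
#' from each subject's map, removing components shared by all subjects (such
#' as the global eccentricity gradient) before intra-pair correlations are
#' computed. Circular maps use the vertex-wise circular mean and wrapped
#' residuals.
#'
#' @param maps Subjects-by-vertices numeric matrix.
#' @param circular Treat values as angles in radians (default FALSE).
#' @return Matrix of residual maps, same shape as \code{maps}.
#' @export
demean_maps <- function(maps, circular = FALSE) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 2) stop_invalid("need at least 2 subjects")
  if (circular) {
    m <- atan2(colMeans(sin(maps)), colMeans(cos(maps)))
    wrap_angle(sweep(maps, 2L, m))
  } else {
    sweep(maps, 2L, colMeans(maps))
  }
}

# Jammalamadaka-SenGupta circular correlation of two angle vectors.
circ_correlation <- function(a, b) {
  sa <- sin(a - circ_mean(a))
  sb <- sin(b - circ_mean(b))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}

#' Intra-pair correlation of residual maps
#'
#' Rank (Spearman) correlation for linear parameters and the
#' Jammalamadaka-SenGupta circular correlation for angles, computed between
#' the two twins of a pair across region vertices. The circular coefficient
#' is invariant to adding a constant rotation to either series.
#'
#' @param res_a,res_b Residual maps of the two twins (numeric vectors).
#' @param method "spearman", "circular" or "pearson".
#' @return Correlation coefficient, or \code{NA} (with a warning) when
#'   either series has zero variance.
#' @export
pair_correlation <- function(res_a, res_b,
                             method = c("spearman", "circular", "pearson")) {
  method <- match.arg(method)
  if (length(res_a) != length(res_b)) stop_invalid("series lengths differ")
  if (length(res_a) < 3) stop_invalid("need at least 3 paired observations")
  if (any(!is.finite(res_a)) || any(!is.finite(res_b))) {
    stop_invalid("series must be finite")
  }
  r <- if (method == "circular") {
    circ_correlation(res_a, res_b)
  } else {
    if (stats::sd(res_a) == 0 || stats::sd(res_b) == 0) NA_real_
    else stats::cor(res_a, res_b, method = method)
  }
  if (is.na(r)) warning("zero variance in a series; correlation undefined")
  r
}

#' Intra-pair correlations for every twin pair of a cohort
#'
#' De-means the maps across the whole participant sample (both zygosity
#' groups together) and computes one intra-pair correlation per twin pair:
#' circular correlation for polar angle, Spearman correlation otherwise.
#'
#' @param cohort A \code{twin_cohort}.
#' @param parameter One of "polar", "ecc", "sigma", "curvature", "thickness".
#' @param region Region label (ignored when \code{vertices} is given).
#' @param vertices Optional explicit vertex subset (e.g. from
#'   \code{\link{subsample_vertices}}).
#' @param demean Remove the sample-mean pattern first (default TRUE).
#' @return Data frame with \code{pair_id}, \code{zygosity},
#'   \code{parameter}, \code{region}, \code{method}, \code{r}.
#' @export
cohort_correlations <- function(cohort, parameter, region = NULL,
                                vertices = NULL, demean = TRUE) {
  if (is.null(vertices)) {
    if (is.null(region)) stop_invalid("give either region or vertices")
    vertices <- region_vertices(cohort$surface, region)
  }
  circular <- parameter == "polar"
  x <- cohort_parameter_matrix(cohort, parameter, vertices)
  if (demean) x <- demean_maps(x, circular = circular)
  pairs <- cohort_pairs(cohort)
  method <- if (circular) "circular" else "spearman"
  r <- vapply(seq_len(nrow(pairs)), function(p) {
    pair_correlation(x[pairs$i[p], ], x[pairs$j[p], ], method = method)
  }, numeric(1))
  data.frame(pair_id = pairs$pair_id, zygosity = pairs$zygosity,
             parameter = parameter,
             region = if (is.null(region)) NA_character_ else region,
             method = method, r = r, stringsAsFactors = FALSE)
}

#' Fisher-z group mean of correlation coefficients
#'
#' Averages correlations after Fisher's z-transformation (atanh) and, by
#' default, back-transforms the mean with tanh.
#'
#' @param r Vector of correlation coefficients with \code{|r| < 1}.
#' @param transform "back" (default) returns \code{tanh(mean(atanh(r)))};
#'   "z" returns the z-space mean itself.
#' @return The group mean correlation (or z value).
#' @export
group_mean_correlation <- function(r, transform = c("back", "z")) {
  transform <- match.arg(transform)
  if (length(r) == 0L) stop_invalid("empty correlation list")
  if (any(abs(r) >= 1)) stop_invalid("|r| = 1 gives an infinite Fisher z")
  z <- mean(atanh(r))
  if (transform == "back") tanh(z) else z
}

# Fisher-z mean with clamping, tolerant of degenerate |r| = 1 inputs;
# used inside permutation loops where exact unity can arise by construction.
fisher_mean <- function(r) {
  tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
}

#' Falconer-style correlation difference
#'
#' \code{delta_r = 2 * (M(r_MZ) - M(r_DZ))}, expressed as a percentage:
#' twice the difference of the group mean correlations, times 100. Because
#' the within-pair correlations are within-subject map correlations rather
#' than between-subject intra-class correlations, this measure is reported
#' as a correlation difference, not a classical heritability.
#'
#' @param mean_mz,mean_dz Group mean correlations, in [-1, 1].
#' @return The correlation difference in percent.
#' @examples
#' delta_r(0.53, 0.47)  # 12
#' @export
delta_r <- function(mean_mz, mean_dz) {
  if (any(abs(c(mean_mz, mean_dz)) > 1)) {
    stop_invalid("mean correlations must lie in [-1, 1]")
  }
  200 * (mean_mz - mean_dz)
}

#' Bootstrap test of the correlation difference
#'
#' Resamples the per-pair correlation coefficients with replacement within
#' each zygosity group, recomputes the Fisher-z group means and the
#' correlation difference for each draw, and reports the 2.5th/97.5th
#' percentile confidence interval together with the one-sided bootstrap
#' p-value: the proportion of draws with a correlation difference at or
#' below zero. Significance is judged against a Bonferroni-corrected alpha
#' (default 0.05/9, the family of three pRF parameters by three regions; use
#' \code{n_tests = 6} for the two morphology parameters by three regions).
#'
#' @param r_mz,r_dz Per-pair correlations of the MZ and DZ groups.
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed Optional integer seed; NULL continues the current RNG stream.
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_tests Bonferroni family size (default 9).
#' @param transform Group-mean convention passed to
#'   \code{\link{group_mean_correlation}}: back-transformed mean (default)
#'   or z-space mean.
#' @return A \code{delta_r_result}: list with \code{delta_r} (percent),
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{significant},
#'   \code{alpha_corrected}, \code{m_mz}, \code{m_dz} and the bootstrap
#'   \code{draws}.
#' @export
bootstrap_delta_r <- function(r_mz, r_dz, n_boot = 10000L, seed = NULL,
                              alpha = 0.05, n_tests = 9L,
                              transform = c("back", "z")) {
  transform <- match.arg(transform)
  if (length(r_mz) < 2 || length(r_dz) < 2) {
    stop_invalid("need at least 2 pairs per group")
  }
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")
  if (n_boot < 100) warning("n_boot < 100 gives a very coarse bootstrap")
  maybe_seed(seed)
  zm <- atanh(pmin(pmax(r_mz, -1 + 1e-12), 1 - 1e-12))
  zd <- atanh(pmin(pmax(r_dz, -1 + 1e-12), 1 - 1e-12))
  nm <- length(zm)
  nd <- length(zd)
  bm <- matrix(zm[sample.int(nm, nm * n_boot, replace = TRUE)], n_boot, nm)
  bd <- matrix(zd[sample.int(nd, nd * n_boot, replace = TRUE)], n_boot, nd)
  back <- function(z) if (transform == "back") tanh(z) else z
  draws <- 200 * (back(rowMeans(bm)) - back(rowMeans(bd)))
  m_mz <- back(mean(zm))
  m_dz <- back(mean(zd))
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  p <- mean(draws <= 0)
  structure(list(delta_r = 200 * (m_mz - m_dz),
                 ci_low = ci[1], ci_high = ci[2], p = p,
                 significant = p < alpha / n_tests,
                 alpha_corrected = alpha / n_tests,
                 m_mz = m_mz, m_dz = m_dz, transform = transform,
                 n_boot = as.integer(n_boot), draws = draws),
            class = "delta_r_result")
}

#' @export
print.delta_r_result <- function(x, ...) {
  cat(sprintf("Correlation difference: %.2f%% [%.2f, %.2f], p = %.4g%s\n",
              x$delta_r, x$ci_low, x$ci_high, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Trend of the correlation difference across the visual hierarchy
#'
#' Fits, for each bootstrap iteration, an ordinary least-squares regression
#' of the correlation-difference draws on the region rank (dummy coded 1, 2,
#' 3, ...) and reports the proportion of iterations with a slope at or below
#' zero.
#'
#' @param draws_list List of bootstrap draw vectors, one per region in
#'   hierarchy order, with matched iteration counts.
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_tests Bonferroni family size (default 3, one trend per pRF
#'   parameter).
#' @return List with \code{slopes} (per-iteration), \code{slope} (their
#'   mean), \code{p}, \code{significant}, \code{alpha_corrected}.
#' @export
hierarchy_trend <- function(draws_list, alpha = 0.05, n_tests = 3L) {
  k <- length(draws_list)
  if (k < 2) stop_invalid("need at least two regions")
  n <- unique(lengths(draws_list))
  if (length(n) != 1L) stop_invalid("iteration counts differ between regions")
  y <- do.call(cbind, draws_list)
  xc <- seq_len(k) - (k + 1) / 2
  slopes <- as.numeric(y %*% xc) / sum(xc^2)
  p <- mean(slopes <= 0)
  list(slopes = slopes, slope = mean(slopes), p = p,
       significant = p < alpha / n_tests, alpha_corrected = alpha / n_tests)
}

# Pairwise correlation matrix among a set of residual maps (rows), using the
# same coefficient as the observed analysis. Spearman reduces to Pearson on
# ranks; the circular coefficient factorizes into per-subject sine residuals.
pairwise_correlations <- function(x, method) {
  if (method == "circular") {
    s <- t(apply(x, 1L, function(a) sin(a - circ_mean(a))))
    cp <- tcrossprod(s)
    d <- sqrt(diag(cp))
    cp / outer(d, d)
  } else {
    rk <- t(apply(x, 1L, rank))
    stats::cor(t(rk))
  }
}

#' Permutation test of the mean intra-pair correlation
#'
#' Breaks up the twin pairs of one zygosity group by shuffling its
#' participants into pseudo-random pairs \code{n_perm} times (never
#' re-creating a true pair) and reports the proportion of resamples whose
#' mean intra-pair correlation is greater than or equal to the observed
#' one. De-meaning (over the whole sample) and the correlation coefficient
#' are identical to the observed analysis.
#'
#' @inheritParams cohort_correlations
#' @param group Zygosity group, "MZ" or "DZ".
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param smoothed If TRUE, report \code{(b + 1) / (n_perm + 1)}.
#' @return List with \code{p}, \code{observed} (Fisher-z mean correlation of
#'   the true pairs) and \code{perm} (null distribution).
#' @export
permutation_correlation_test <- function(cohort, parameter, region = NULL,
                                         group = "MZ", vertices = NULL,
                                         n_perm = 1000L, seed = 1L,
                                         smoothed = FALSE) {
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  if (is.null(vertices)) {
    if (is.null(region)) stop_invalid("give either region or vertices")
    vertices <- region_vertices(cohort$surface, region)
  }
  circular <- parameter == "polar"
  x <- demean_maps(cohort_parameter_matrix(cohort, parameter, vertices),
                   circular = circular)
  pairs <- cohort_pairs(cohort, group)
  if (nrow(pairs) < 3) stop_invalid("need at least 3 pairs in the group")
  subj_idx <- c(rbind(pairs$i, pairs$j))
  m <- length(subj_idx)
  cmat <- pairwise_correlations(x[subj_idx, , drop = FALSE],
                                if (circular) "circular" else "spearman")
  true_local <- matrix(seq_len(m), ncol = 2, byrow = TRUE)
  observed <- fisher_mean(cmat[true_local])
  true_key <- paste(true_local[, 1], true_local[, 2])
  maybe_seed(derive_seed(seed, paste("permcorr", parameter, group)))
  perm <- vapply(seq_len(n_perm), function(k) {
    fisher_mean(cmat[pseudo_pairing(m, true_key)])
  }, numeric(1))
  b <- sum(perm >= observed)
  p <- if (smoothed) (b + 1) / (n_perm + 1) else b / n_perm
  list(p = p, observed = observed, perm = perm)
}

#' Alignment transformation magnitudes and their twin correlation
#'
#' For every vertex of a region, the Euclidean distance between a subject's
#' native coordinates and the aligned (template) coordinates is computed and
#' averaged over the region; the per-subject mean displacements are then
#' correlated between co-twins within each zygosity group. An uncorrelated
#' result indicates that the magnitude of the spatial normalization applied
#' to each brain carries no twin resemblance.
#'
#' @param cohort A \code{twin_cohort}.
#' @param region Region label.
#' @return List with \code{subjects} (per-subject mean displacement, mm) and
#'   \code{groups} (per-zygosity Pearson correlation across pairs with
#'   p-value; \code{NA} when undefined).
#' @export
transformation_magnitude <- function(cohort, region) {
  verts <- region_vertices(cohort$surface, region)
  meta <- cohort_meta(cohort)
  meta$mean_displacement <- vapply(cohort$subjects, function(s) {
    d <- s$native_coord[verts, , drop = FALSE] -
      s$aligned_coord[verts, , drop = FALSE]
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  groups <- do.call(rbind, lapply(c("MZ", "DZ"), function(g) {
    pairs <- cohort_pairs(cohort, g)
    t1 <- meta$mean_displacement[pairs$i]
    t2 <- meta$mean_displacement[pairs$j]
    if (nrow(pairs) < 3 || stats::sd(t1) == 0 || stats::sd(t2) == 0) {
      data.frame(zygosity = g, r = NA_real_, p = NA_real_,
                 n_pairs = nrow(pairs), stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(t1, t2)
      data.frame(zygosity = g, r = unname(ct$estimate), p = ct$p.value,
                 n_pairs = nrow(pairs), stringsAsFactors = FALSE)
    }
  }))
  list(subjects = meta[, c("subject_id", "pair_id", "zygosity",
                           "mean_displacement")],
       groups = groups)
}

# Moment (Haseman-Elston style) regression of off-diagonal phenotypic
# similarity on kinship plus a co-twin (shared environment) indicator.
# Returns c(h2, c2) before clipping.
he_regress <- function(s, kin, cotwin) {
  fit <- stats::lm.fit(cbind(1, kin, cotwin), s)
  unname(fit$coefficients[2:3])
}

#' Multidimensional heritability from the phenotypic similarity matrix
#'
#' Estimates heritability of a multivariate (vertex-wise) phenotype from the
#' full subject-by-subject phenotypic similarity matrix and the expected
#' genetic kinship matrix (1 for MZ co-twins, 0.5 for DZ co-twins, 0 for
#' unrelated). Similarity is the correlation between the subjects'
#' vertex-wise de-meaned phenotype vectors. The estimator regresses the
#' off-diagonal similarities on kinship and a co-twin indicator (a moment
#' estimator in the Haseman-Elston tradition); the co-twin indicator absorbs
#' shared-environment resemblance so that the kinship coefficient estimates
#' \code{h2 = 2 * (r_MZ - r_DZ)}, clipped into [0, 1]. Confidence intervals
#' come from resampling twin pairs within each group.
#'
#' @param pheno Subjects-by-vertices numeric phenotype matrix.
#' @param meta Data frame aligned with the rows of \code{pheno}, with
#'   columns \code{pair_id} and \code{zygosity}.
#' @param n_boot Bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @param alpha CI level (default 0.05, i.e. a 95 percent interval).
#' @return An \code{h2_estimate}: list with \code{h2}, \code{c2},
#'   \code{ci_low}, \code{ci_high}, \code{draws}, \code{n_boot}.
#' @export
multidim_h2 <- function(pheno, meta, n_boot = 10000L, seed = 1L,
                        alpha = 0.05) {
  pheno <- as.matrix(pheno)
  if (ncol(pheno) < 2) stop_invalid("need at least 2 vertices")
  if (nrow(pheno) != nrow(meta)) stop_invalid("pheno and meta disagree")
  x <- sweep(pheno, 2L, colMeans(pheno))
  if (any(apply(x, 1L, stats::sd) == 0)) {
    stop_invalid("phenotype is constant for at least one subject")
  }
  s_mat <- stats::cor(t(x))

  pair_of <- meta$pair_id
  zyg_of <- meta$zygosity
  pair_ids <- unique(pair_of)
  pair_zyg <- zyg_of[match(pair_ids, pair_of)]
  if (sum(pair_zyg == "MZ") < 2 || sum(pair_zyg == "DZ") < 2) {
    stop_invalid("need at least 2 pairs per zygosity group")
  }
  pair_rows <- lapply(pair_ids, function(p) which(pair_of == p))
  if (any(lengths(pair_rows) != 2)) stop_invalid("every pair needs 2 members")

  n <- nrow(pheno)
  ut <- which(upper.tri(s_mat))
  ui <- row(s_mat)[ut]
  uj <- col(s_mat)[ut]

  est_from <- function(orig, samp_pair, samp_zyg) {
    oi <- orig[ui]
    oj <- orig[uj]
    same <- samp_pair[ui] == samp_pair[uj]
    # drop duplicated-subject self-similarities and cross-copy entries of a
    # pair drawn more than once, which would mislabel co-twins as unrelated
    ok <- oi != oj & !(pair_of[oi] == pair_of[oj] & !same)
    kin <- ifelse(same, ifelse(samp_zyg[ui] == "MZ", 1, 0.5), 0)
    he_regress(s_mat[cbind(oi, oj)][ok], kin[ok], as.numeric(same)[ok])
  }

  samp_pair0 <- match(pair_of, pair_ids)
  coefs <- est_from(seq_len(n), samp_pair0, zyg_of)
  h2 <- min(max(coefs[1], 0), 1)

  maybe_seed(derive_seed(seed, "multidim_h2"))
  mz_pairs <- which(pair_zyg == "MZ")
  dz_pairs <- which(pair_zyg == "DZ")
  draws <- vapply(seq_len(n_boot), function(b) {
    sel <- c(sample(mz_pairs, length(mz_pairs), replace = TRUE),
             sample(dz_pairs, length(dz_pairs), replace = TRUE))
    orig <- unlist(pair_rows[sel])
    samp_pair <- rep(seq_along(sel), each = 2L)
    samp_zyg <- rep(pair_zyg[sel], each = 2L)
    min(max(est_from(orig, samp_pair, samp_zyg)[1], 0), 1)
  }, numeric(1))
  ci <- unname(stats::quantile(draws, c(alpha / 2, 1 - alpha / 2)))
  structure(list(h2 = h2, c2 = coefs[2], ci_low = ci[1], ci_high = ci[2],
                 draws = draws, n_boot = as.integer(n_boot)),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.3f [%.3f, %.3f] (%d bootstrap draws)\n",
              x$h2, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
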