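#' Configuration of a full analysis run
#'
#' Bundles every stage setting behind one validated object. Stage toggles
#' select which analyses run; draw counts default to reduced values suitable
#' for an interactive demonstration and can be raised to the full settings
#' (10000 bootstrap draws, 1000 permutations, 1000 power replicates).
#'
#' @param seed Master seed; every stage derives an independent substream.
#' @param out_dir Output directory.
#' @param n_vertices_per_region Region sizes for the simulated surface.
#' @param generator A \code{\link{generator_config}} (its seed is replaced
#'   by the pipeline seed).
#' @param regions Regions to analyze.
#' @param stages Character vector from \code{c("overlap", "similarity",
#'   "corr", "morphology", "controls", "h2", "power")}.
#' @param n_boot Bootstrap draws for correlation-difference tests.
#' @param n_perm Permutations for the permutation tests.
#' @param h2_boot Bootstrap draws for heritability CIs.
#' @param power_reps,power_boot,power_grid Power-simulation settings.
#' @param min_dist Minimum vertex separation (mm) of the subsampling control.
#' @return A validated \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, out_dir,
                            n_vertices_per_region = c(V1 = 480L, V2 = 400L,
                                                      V3 = 324L),
                            generator = generator_config(),
                            regions = c("V1", "V2", "V3"),
                            stages = c("overlap", "similarity", "corr",
                                       "morphology", "controls", "h2",
                                       "power"),
                            n_boot = 2000L, n_perm = 200L, h2_boot = 500L,
                            power_reps = 100L, power_boot = 2000L,
                            power_grid = c(0, 4, 12), min_dist = 8) {
  known <- c("overlap", "similarity", "corr", "morphology", "controls",
             "h2", "power")
  if (length(bad <- setdiff(stages, known))) {
    stop_invalid("unknown stages: ", paste(bad, collapse = ", "))
  }
  if (missing(out_dir)) stop_invalid("out_dir is required")
  if (!inherits(generator, "generator_config")) {
    stop_invalid("generator must be a generator_config")
  }
  if (any(c(n_boot, n_perm, h2_boot, power_reps, power_boot) < 1)) {
    stop_invalid("draw counts must be positive")
  }
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_vertices_per_region = n_vertices_per_region,
                 generator = generator, regions = regions, stages = stages,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 h2_boot = as.integer(h2_boot),
                 power_reps = as.integer(power_reps),
                 power_boot = as.integer(power_boot),
                 power_grid = power_grid, min_dist = min_dist),
            class = "pipeline_config")
}

write_stage_csv <- function(tab, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(tab, path, row.names = FALSE)
  path
}

delta_r_table <- function(cohort, parameters, regions, n_boot, n_tests,
                          seed, vertices = NULL) {
  rows <- list()
  draws <- list()
  for (param in parameters) {
    for (reg in regions) {
      cs <- cohort_correlations(cohort, param, region = reg,
                                vertices = vertices[[reg]])
      res <- bootstrap_delta_r(cs$r[cs$zygosity == "MZ"],
                               cs$r[cs$zygosity == "DZ"],
                               n_boot = n_boot, n_tests = n_tests,
                               seed = derive_seed(seed,
                                                  paste("dr", param, reg)))
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, region = reg, delta_r = res$delta_r,
        ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
        significant = res$significant, m_mz = res$m_mz, m_dz = res$m_dz,
        stringsAsFactors = FALSE)
      draws[[paste(param, reg)]] <- res$draws
    }
  }
  list(table = do.call(rbind, rows), draws = draws)
}

#' Run the full simulated twin analysis pipeline
#'
#' Generates a twin cohort (functional maps, morphology, alignment
#' displacements), writes it to disk, and executes the selected analysis
#' stages, writing per-stage CSV/JSON outputs under \code{out_dir}. The run
#' is deterministic given the seed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A \code{run_report}: list of stage output paths and in-memory
#'   summary tables.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("config must be a pipeline_config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  tables <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  surface <- stage("simulate", build_surface(config$n_vertices_per_region))
  template <- stage("simulate", generate_template_map(surface))
  cohort <- stage("simulate",
                  generate_twin_cohort(surface, template, config$generator))
  cohort <- stage("simulate", generate_morphology_maps(cohort))
  cohort <- stage("simulate",
                  generate_alignment_coordinates(cohort,
                                                 seed = config$seed))
  outputs$cohort <- stage("simulate",
                          write_cohort(cohort,
                                       file.path(config$out_dir, "cohort")))

  if ("overlap" %in% config$stages) {
    stage("overlap", {
      sc <- region_overlap_scores(cohort, config$regions)
      outputs$overlap_scores <- write_stage_csv(sc, config$out_dir,
                                                "overlap_scores.csv")
      av <- two_way_anova(data.frame(value = sc$jaccard,
                                     zygosity = sc$zygosity,
                                     region = sc$region))
      perms <- expand.grid(region = config$regions, group = c("MZ", "DZ"),
                           stringsAsFactors = FALSE)
      perms$p <- mapply(function(reg, g) {
        permutation_overlap_test(cohort, reg, g, n_perm = config$n_perm,
                                 seed = config$seed)$p
      }, perms$region, perms$group)
      outputs$overlap_summary <- file.path(config$out_dir,
                                           "overlap_summary.json")
      jsonlite::write_json(list(anova = av, permutation = perms),
                           outputs$overlap_summary, auto_unbox = TRUE,
                           digits = NA)
      tables$overlap <- sc
      tables$overlap_anova <- av
      tables$overlap_perm <- perms
    })
  }

  if ("similarity" %in% config$stages) {
    stage("similarity", {
      sc <- map_similarity_scores(cohort, config$regions)
      outputs$similarity_scores <- write_stage_csv(sc, config$out_dir,
                                                   "similarity_scores.csv")
      av <- two_way_anova(data.frame(value = sc$log_similarity,
                                     zygosity = sc$zygosity,
                                     region = sc$region))
      outputs$similarity_summary <- file.path(config$out_dir,
                                              "similarity_summary.json")
      jsonlite::write_json(list(anova = av), outputs$similarity_summary,
                           auto_unbox = TRUE, digits = NA)
      tables$similarity <- sc
      tables$similarity_anova <- av
    })
  }

  prf_params <- c("polar", "ecc", "sigma")
  if ("corr" %in% config$stages) {
    stage("corr", {
      cs <- do.call(rbind, lapply(prf_params, function(pm) {
        do.call(rbind, lapply(config$regions, function(rg) {
          cohort_correlations(cohort, pm, region = rg)
        }))
      }))
      outputs$correlations <- write_stage_csv(cs, config$out_dir,
                                              "correlations.csv")
      dr <- delta_r_table(cohort, prf_params, config$regions,
                          config$n_boot, n_tests = 9L, seed = config$seed)
      outputs$delta_r <- write_stage_csv(dr$table, config$out_dir,
                                         "delta_r.csv")
      trend <- do.call(rbind, lapply(prf_params, function(pm) {
        ht <- hierarchy_trend(lapply(config$regions, function(rg) {
          dr$draws[[paste(pm, rg)]]
        }))
        data.frame(parameter = pm, slope = ht$slope, p = ht$p,
                   significant = ht$significant, stringsAsFactors = FALSE)
      }))
      outputs$hierarchy_trend <- write_stage_csv(trend, config$out_dir,
                                                 "hierarchy_trend.csv")
      perms <- expand.grid(parameter = prf_params, region = config$regions,
                           group = c("MZ", "DZ"), stringsAsFactors = FALSE)
      perms$p <- mapply(function(pm, rg, g) {
        permutation_correlation_test(cohort, pm, region = rg, group = g,
                                     n_perm = config$n_perm,
                                     seed = config$seed)$p
      }, perms$parameter, perms$region, perms$group)
      outputs$correlation_perm <- write_stage_csv(perms, config$out_dir,
                                                  "correlation_perm.csv")
      tables$correlations <- cs
      tables$delta_r <- dr$table
      tables$hierarchy_trend <- trend
      tables$correlation_perm <- perms
    })
  }

  if ("morphology" %in% config$stages) {
    stage("morphology", {
      dr <- delta_r_table(cohort, c("curvature", "thickness"),
                          config$regions, config$n_boot, n_tests = 6L,
                          seed = config$seed)
      outputs$morphology_delta_r <- write_stage_csv(dr$table,
                                                    config$out_dir,
                                                    "morphology_delta_r.csv")
      tables$morphology_delta_r <- dr$table
    })
  }

  if ("controls" %in% config$stages) {
    stage("controls", {
      verts <- lapply(config$regions, function(rg) {
        subsample_vertices(cohort$surface, rg, min_dist = config$min_dist,
                           seed = derive_seed(config$seed, paste0("sub", rg)))
      })
      names(verts) <- config$regions
      dr <- delta_r_table(cohort, prf_params, config$regions,
                          config$n_boot, n_tests = 9L,
                          seed = derive_seed(config$seed, "subsampled"),
                          vertices = verts)
      outputs$subsampled_delta_r <- write_stage_csv(dr$table,
                                                    config$out_dir,
                                                    "subsampled_delta_r.csv")
      tm <- do.call(rbind, lapply(config$regions, function(rg) {
        g <- transformation_magnitude(cohort, rg)$groups
        g$region <- rg
        g
      }))
      outputs$transformation <- write_stage_csv(tm, config$out_dir,
                                                "transformation_magnitude.csv")
      tables$subsampled_delta_r <- dr$table
      tables$transformation <- tm
    })
  }

  if ("h2" %in% config$stages) {
    stage("h2", {
      meta <- cohort_meta(cohort)
      rows <- list()
      for (pm in prf_params) {
        for (rg in config$regions) {
          verts <- region_vertices(cohort$surface, rg)
          pheno <- demean_maps(cohort_parameter_matrix(cohort, pm, verts),
                               circular = pm == "polar")
          h <- multidim_h2(pheno, meta, n_boot = config$h2_boot,
                           seed = derive_seed(config$seed,
                                              paste("h2", pm, rg)))
          rows[[length(rows) + 1L]] <- data.frame(
            parameter = pm, region = rg, h2 = h$h2,
            ci_low = h$ci_low, ci_high = h$ci_high, stringsAsFactors = FALSE)
        }
      }
      tables$h2 <- do.call(rbind, rows)
      outputs$h2 <- write_stage_csv(tables$h2, config$out_dir, "h2.csv")
    })
  }

  if ("power" %in% config$stages) {
    stage("power", {
      sc <- power_scenario(delta_r_grid = config$power_grid,
                           n_reps = config$power_reps,
                           n_boot = config$power_boot,
                           seed = derive_seed(config$seed, "power"))
      pc <- run_power_curve(sc)
      outputs$power <- write_stage_csv(as.data.frame(pc), config$out_dir,
                                       "power_curve.csv")
      tables$power <- pc
    })
  }

  report <- structure(list(out_dir = config$out_dir, seed = config$seed,
                           stages = config$stages, outputs = outputs,
                           tables = tables),
                      class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ") with stages:",
      paste(x$stages, collapse = ", "), "\n")
  cat("Outputs under:", x$out_dir, "\n")
  invisible(x)
}

md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Assemble a Markdown summary report of a pipeline run
#'
#' @param report A \code{run_report} from \code{\link{run_pipeline}}.
#' @param path Output file (default \code{report.md} in the run directory).
#' @return The report path, invisibly. Missing stage outputs produce a
#'   warning and a partial report.
#' @export
make_report <- function(report, path = file.path(report$out_dir, "report.md")) {
  sections <- c("# Twin retinotopy analysis report", "",
                paste("Seed:", report$seed), "")
  want <- c(overlap_anova = "Region overlap: two-way ANOVA",
            overlap_perm = "Region overlap: permutation p-values",
            similarity_anova = "Map similarity (log): two-way ANOVA",
            delta_r = "Correlation differences (pRF parameters)",
            hierarchy_trend = "Hierarchy trend of the correlation difference",
            correlation_perm = "Permutation p-values of intra-pair correlations",
            morphology_delta_r = "Correlation differences (morphology)",
            subsampled_delta_r = "Correlation differences (8 mm subsampled)",
            transformation = "Alignment transformation magnitudes",
            h2 = "Multidimensional heritability",
            power = "Power curve")
  missing <- character(0)
  for (key in names(want)) {
    stage_of <- switch(key,
                       overlap_anova = , overlap_perm = "overlap",
                       similarity_anova = "similarity",
                       delta_r = , hierarchy_trend = ,
                       correlation_perm = "corr",
                       morphology_delta_r = "morphology",
                       subsampled_delta_r = , transformation = "controls",
                       key)
    if (!stage_of %in% report$stages) next
    tab <- report$tables[[key]]
    if (is.null(tab)) {
      missing <- c(missing, key)
      next
    }
    sections <- c(sections, paste("##", want[[key]]), "",
                  md_table(as.data.frame(tab)), "")
  }
  if (length(missing)) {
    warning("missing stage outputs: ", paste(missing, collapse = ", "),
            "; report is partial")
  }
  writeLines(sections, path)
  invisible(path)
}
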