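#' Full pipeline configuration
#'
#' Bundles every tunable constant of the analysis in one place: the
#' synthetic-landscape settings (or paths to real inputs), the 0.8 screening
#' ceiling, the niche-model settings (10-fold cross-validation, 0.0005
#' convergence, 10000 background points), the four suitability classes and
#' the content grade definitions.
#'
#' @param out_dir directory where all artifacts are written.
#' @param seed master RNG seed; every stochastic stage derives its seed from
#'   it.
#' @param synthetic a [synthetic_config()]; its own seed is overridden by
#'   `seed`.
#' @param screening_threshold pairwise correlation ceiling (default 0.8).
#' @param screening_priority optional priority list for [iterative_screen()].
#' @param n_background,beta_multiplier,convergence,max_cycles,k_folds
#'   niche-model settings (see [maxent()] and [cross_validate()]).
#' @param n_classes suitability classes for the natural-breaks step
#'   (default 4).
#' @param grades list of two [content_grades()] definitions.
#' @param zones_nx,zones_ny synthetic zone lattice (see [generate_zones()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synthetic = synthetic_config(),
                            screening_threshold = 0.8,
                            screening_priority = NULL,
                            n_background = 10000, beta_multiplier = 1,
                            convergence = 5e-4, max_cycles = 500,
                            k_folds = 10, n_classes = 4,
                            grades = list(content_grades("astragaloside_iv"),
                                          content_grades("calycosin_7_glucoside")),
                            zones_nx = 2, zones_ny = 2) {
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic,
                 screening_threshold = screening_threshold,
                 screening_priority = screening_priority,
                 n_background = n_background,
                 beta_multiplier = beta_multiplier,
                 convergence = convergence, max_cycles = max_cycles,
                 k_folds = k_folds, n_classes = n_classes, grades = grades,
                 zones_nx = zones_nx, zones_ny = zones_ny),
            class = "pipeline_config")
}

#' Run the end-to-end regionalization pipeline
#'
#' Stages, in order: synthesize the landscape, occurrences and contents;
#' screen factors to the correlation ceiling; cross-validate and fit the
#' niche model on the retained layers; predict suitability; clip to the
#' occurrence-observed range; classify with natural breaks; tabulate zonal
#' areas; correlate and stepwise-regress the contents; project the
#' equations; grade; and overlay the optimum classes. Every intermediate
#' artifact is written under `config$out_dir` and checksummed in the
#' returned manifest. Rerunning with the same config and seed reproduces
#' bit-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return `run_manifest`: list with `config`, `seed`, per-stage timings,
#'   `outputs` (paths and md5 checksums), `counts` (cells masked, factors
#'   dropped, clamped cells, ...), and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  outputs <- character()
  counts <- list()
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }
  emit <- function(path) outputs <<- c(outputs, path)
  out <- function(...) file.path(config$out_dir, ...)

  # --- synthesize -------------------------------------------------------
  synth <- stage("synth", {
    gen <- generate_factor_stack(config$synthetic)
    occ <- generate_occurrences(gen$truth, config$synthetic$n_presences,
                                seed = config$seed + 1L)
    gen$occ <- occ
    gen
  })
  results$truth <- synth$truth
  stage("write_inputs", {
    for (nm in names(synth$stack$layers))
      emit(write_ascii_grid(synth$stack$layers[[nm]],
                            out(paste0(nm, ".asc"))))
    write.csv(synth$occ, out("occurrences.csv"), row.names = FALSE)
    emit(out("occurrences.csv"))
    invisible(NULL)
  })

  # --- screening --------------------------------------------------------
  fm <- stage("extract", extract_at_points(synth$stack, synth$occ))
  screen <- stage("screen",
    iterative_screen(fm, threshold = config$screening_threshold,
                     priority = config$screening_priority))
  results$screening <- screen
  counts$factors_dropped <- nrow(screen$dropped)
  stage("write_screening", {
    emit(write_screening_report(screen, config$out_dir))
    invisible(NULL)
  })
  retained_stack <- raster_stack(synth$stack$layers[screen$retained])

  # --- niche model ------------------------------------------------------
  cv <- stage("cv", cross_validate(
    synth$occ, retained_stack, k = config$k_folds, seed = config$seed,
    n_background = config$n_background,
    beta_multiplier = config$beta_multiplier,
    convergence = config$convergence, max_cycles = config$max_cycles))
  results$cv <- cv
  model <- stage("fit", maxent(
    synth$occ, retained_stack, n_background = config$n_background,
    beta_multiplier = config$beta_multiplier,
    convergence = config$convergence, max_cycles = config$max_cycles,
    seed = config$seed))
  results$model <- model
  results$contribution <- percent_contribution(model)
  stage("write_model", {
    emit(write_maxent_json(model, out("model.json")))
    write.csv(cv$replicates, out("cv_auc.csv"), row.names = FALSE)
    emit(out("cv_auc.csv"))
    invisible(NULL)
  })
  suit <- stage("predict", predict(model, retained_stack))
  stage("write_suitability", emit(write_ascii_grid(suit, out("suitability.asc"))))

  # --- regionalization --------------------------------------------------
  clipped <- stage("clip", clip_to_observed_range(suit, synth$occ))
  counts$cells_masked <- attr(clipped, "masked_cells")
  breaks <- stage("jenks", jenks_breaks(as.vector(clipped$values),
                                        k = config$n_classes,
                                        seed = config$seed))
  results$breaks <- breaks
  classes <- stage("classify", classify_suitability(clipped, breaks))
  stage("write_classes", emit(write_ascii_grid(classes, out("suitability_class.asc"))))
  zones <- generate_zones(suit, config$zones_nx, config$zones_ny)
  zone_raster <- stage("rasterize_zones", rasterize_zones(zones, suit))
  zonal <- stage("zonal_areas", zonal_areas(classes, zone_raster))
  results$zonal <- zonal
  stage("write_zonal", {
    write.csv(zonal, out("zonal_areas.csv"), row.names = FALSE)
    emit(out("zonal_areas.csv"))
    invisible(NULL)
  })

  # --- quality ----------------------------------------------------------
  contents <- stage("contents", generate_compound_contents(
    fm, config$synthetic$content_coefficients, config$synthetic$target_r2,
    seed = config$seed + 2L))
  stage("write_contents", {
    write.csv(contents, out("contents.csv"), row.names = FALSE)
    emit(out("contents.csv"))
    invisible(NULL)
  })
  correlations <- stage("correlate", correlate_with_significance(fm, contents))
  results$correlations <- correlations
  compounds <- setdiff(names(contents), "id")
  reg <- stage("stepwise", lapply(setNames(compounds, compounds), function(co)
    stepwise_regression(contents[[co]], fm, response_name = co)))
  results$regressions <- reg
  content_rasters <- stage("project", lapply(reg, function(r)
    apply_regression_to_stack(r, synth$stack)))
  counts$clamped_cells <- sum(vapply(content_rasters,
                                     function(g) attr(g, "clamped_cells"), 0))
  graded <- stage("grade", lapply(seq_along(config$grades), function(i)
    grade_contents(content_rasters[[i]], config$grades[[i]])))
  stage("write_quality", {
    write.csv(correlations, out("correlations.csv"), row.names = FALSE)
    emit(out("correlations.csv"))
    for (i in seq_along(content_rasters)) {
      emit(write_ascii_grid(content_rasters[[i]],
                            out(paste0(compounds[i], "_content.asc"))))
      emit(write_ascii_grid(graded[[i]],
                            out(paste0(compounds[i], "_grade.asc"))))
    }
    invisible(NULL)
  })
  overlay <- stage("overlay", high_quality_overlay(classes, graded[[1]],
                                                   graded[[2]], zone_raster))
  results$overlay <- overlay
  stage("write_overlay", {
    emit(write_ascii_grid(overlay$mask, out("high_quality_mask.asc")))
    write.csv(overlay$summary, out("high_quality_summary.csv"),
              row.names = FALSE)
    emit(out("high_quality_summary.csv"))
    invisible(NULL)
  })

  manifest <- structure(list(
    seed = config$seed, config = config,
    timings = timings,
    outputs = data.frame(path = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE),
    counts = counts, results = results),
    class = "run_manifest")
  jsonlite::write_json(list(seed = config$seed,
                            outputs = manifest$outputs,
                            counts = counts),
                       out("manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, %d artifacts in %s\n", x$seed,
              nrow(x$outputs), x$config$out_dir))
  cat(sprintf("  mean test AUC %.3f; %d factors dropped; breaks %s\n",
              x$results$cv$mean_test_auc, x$counts$factors_dropped,
              paste(round(x$results$breaks, 3), collapse = ", ")))
  invisible(x)
}

#' Render a run manifest as a markdown summary
#'
#' Mirrors the study's result tables: per-replicate AUC, per-factor percent
#' contribution (summing to 100), the zonal area table, the factor-compound
#' correlation table with significance flags, the fitted content equations
#' and the high-quality overlay summary.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param path optional file to write the markdown to.
#' @return character vector of markdown lines (invisibly if `path` given).
#' @export
report <- function(manifest, path = NULL) {
  r <- manifest$results
  fmt_tab <- function(df) {
    hdr <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1L, function(x) paste("|", paste(x, collapse = " | "), "|"))
    c(hdr, sep, rows)
  }
  lines <- c(
    "# Regionalization run summary",
    sprintf("Seed: %d", manifest$seed), "",
    "## Cross-validated AUC", "",
    fmt_tab(within(r$cv$replicates, {
      train_auc <- sprintf("%.3f", train_auc)
      test_auc <- sprintf("%.3f", test_auc)
    })),
    sprintf("Mean test AUC %.3f (SD %.3f)", r$cv$mean_test_auc,
            r$cv$sd_test_auc), "",
    "## Percent contribution", "",
    fmt_tab(data.frame(factor = names(r$contribution),
                       contribution_pct = sprintf("%.1f", r$contribution))),
    sprintf("Sum: %.1f", sum(r$contribution)), "",
    "## Suitability classes", "",
    sprintf("Natural-break bounds: %s",
            paste(sprintf("%.3f", r$breaks), collapse = ", ")), "",
    "## Zonal areas", "",
    fmt_tab(r$zonal), "",
    "## Factor-content correlations", "",
    fmt_tab(within(r$correlations, {
      r <- sprintf("%.2f", r); p <- sprintf("%.4f", p)
    })), "",
    "## Content equations", "",
    vapply(r$regressions, function(m)
      sprintf("- %s: R2 = %.3f, terms: %s", m$response, m$r_squared,
              paste(m$selected, collapse = ", ")), ""), "",
    "## High-quality overlay", "",
    fmt_tab(r$overlay$summary))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
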