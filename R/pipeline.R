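#' Run configuration for the end-to-end pipeline
#'
#' Collects every knob of a full simulate-reconstruct-analyze-stats run in
#' one serializable object. `write_run_config()` / `read_run_config()`
#' round-trip it through YAML (or JSON), so a stored config reproduces the
#' run exactly.
#'
#' @param n_subjects simulated subjects (paired rest/stress).
#' @param seed master seed; every random draw in the run derives from it.
#' @param venc,voxel_mm,n_frames,snr acquisition surrogate parameters, see
#'   [acquisition_config()].
#' @param rho blood density (kg/m^3).
#' @param geometry_params list of arguments for [aorta_geometry()].
#' @param ranges cohort sampling ranges, see [cohort_ranges()].
#' @param region_cuts arc-length cut points `c(s1, s2)` for
#'   [divide_regions()].
#' @param unwrap unwrap stages to run, subset of
#'   `c("temporal", "laplacian")`.
#' @param keep_maps write per-subject map files (`.rds`) into the run
#'   directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_subjects = 12, seed = 1, venc = 1.4,
                       voxel_mm = 2.8, n_frames = 20L, snr = 30,
                       rho = 1060, geometry_params = list(),
                       ranges = cohort_ranges(),
                       region_cuts = c(0.376, 0.510),
                       unwrap = c("temporal", "laplacian"),
                       keep_maps = FALSE) {
  stopifnot(n_subjects >= 2, length(region_cuts) == 2L)
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), venc = venc, voxel_mm = voxel_mm,
                 n_frames = as.integer(n_frames), snr = snr, rho = rho,
                 geometry_params = geometry_params, ranges = ranges,
                 region_cuts = region_cuts,
                 unwrap = match.arg(unwrap, several.ok = TRUE),
                 keep_maps = isTRUE(keep_maps)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path file path; extension `.yaml`/`.yml` uses YAML (requires the
#'   `yaml` package), anything else JSON.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$ranges <- lapply(x$ranges, as.numeric)
  do.call(run_config, c(x[setdiff(names(x), "keep_maps")],
                        list(keep_maps = isTRUE(x$keep_maps))))
}

#' Run the full pipeline: simulate, reconstruct, analyze, statistics
#'
#' Simulates a paired rest/stress cohort on the analytic aortic geometry,
#' synthesizes MR signals per subject and condition, reconstructs velocity
#' and TKE maps (with the configured unwrap chain), reduces them to regional
#' parameter time series and cycle peaks, assembles the recovered cohort
#' table and computes the statistical layer: normality-gated paired
#' rest-vs-stress tests, group fold changes, regressions of peak total TKE
#' on cardiac output / stroke volume / heart rate (both conditions pooled),
#' a ground-truth-versus-recovered comparison per subject, and the
#' printed-table arithmetic report. The run is deterministic given the
#' config seed.
#'
#' @param cfg a `run_config`.
#' @param out_dir optional run directory; when given, `params.csv`,
#'   `peaks.csv`, `cohort.csv`, `stats.json` (and per-subject map files if
#'   `keep_maps`) are written there.
#' @param verbose print stage progress.
#' @return an object of class `pipeline_run`: `cohort_table` (recovered),
#'   `truth`, `params` (long time-series table), `peaks`, `stats` (list),
#'   `recovery` (ground-truth comparison), `arithmetic`, `config`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  acq <- acquisition_config(venc = cfg$venc, voxel_mm = cfg$voxel_mm,
                            n_frames = cfg$n_frames, snr = cfg$snr,
                            rho = cfg$rho)
  say("geometry")
  geometry <- stage("geometry", do.call(aorta_geometry, c(
    list(voxel_mm = cfg$voxel_mm), cfg$geometry_params)))
  regions <- stage("regions", divide_regions(geometry, cfg$region_cuts[1],
                                             cfg$region_cuts[2]))
  say("cohort (%d subjects, seed %d)", cfg$n_subjects, cfg$seed)
  cohort <- stage("cohort", make_cohort(cfg$n_subjects, cfg$seed,
                                        cfg$ranges, geometry, acq))

  params <- list(); peaks <- list(); recovery <- list()
  for (i in seq_len(cfg$n_subjects)) {
    for (cond in c("rest", "stress")) {
      id <- cohort$subjects[[i]]$id
      say("subject %s / %s", id, cond)
      ds <- stage("simulate", realize_subject(cohort, i, cond, geometry, acq))
      maps <- stage("reconstruct",
                    reconstruct_maps(ds$signals, rho = cfg$rho,
                                     unwrap = cfg$unwrap))
      ts <- stage("analyze",
                  timeseries_parameters(maps$velocity, maps$tke,
                                        maps$tke_filtered, regions))
      pk <- peak_parameters(ts)
      ts$subject <- id; ts$condition <- cond
      pk$subject <- id; pk$condition <- cond
      params[[length(params) + 1L]] <- ts
      peaks[[length(peaks) + 1L]] <- pk

      gt <- cohort$truth[cohort$truth$subject == id &
                           cohort$truth$condition == cond, ]
      rec_tke <- pk$peak_value[pk$region == "TAo" &
                                 pk$parameter == "tke_total"]
      recovery[[length(recovery) + 1L]] <- data.frame(
        subject = id, condition = cond,
        gt_peak_tke_total = gt$gt_peak_tke_total,
        recovered_peak_tke_total = rec_tke,
        rel_error = (rec_tke - gt$gt_peak_tke_total) /
          gt$gt_peak_tke_total)
      if (cfg$keep_maps && !is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(maps, file.path(out_dir,
                                sprintf("maps_%s_%s.rds", id, cond)))
      }
    }
  }
  params <- do.call(rbind, params)
  peaks <- do.call(rbind, peaks)
  recovery <- do.call(rbind, recovery)

  say("statistics")
  cohort_table <- stage("cohort-table",
                        build_cohort_table(cohort$truth, peaks))
  stats <- stage("stats", cohort_statistics(cohort_table))
  arithmetic <- stage("arithmetic", reproduce_table_arithmetic())

  run <- structure(list(cohort_table = cohort_table, truth = cohort$truth,
                        params = params, peaks = peaks, stats = stats,
                        recovery = recovery, arithmetic = arithmetic,
                        volumes_ml = regions$volumes_ml, config = cfg),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(params, file.path(out_dir, "params.csv"),
                     row.names = FALSE)
    utils::write.csv(peaks, file.path(out_dir, "peaks.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort_table, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(stats = stats, recovery = recovery, arithmetic = arithmetic,
           volumes_ml = as.list(run$volumes_ml),
           config = unclass(cfg)),
      file.path(out_dir, "stats.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE, force = TRUE)
  }
  run
}

# Wide per-subject/condition table: clinical scalars + the five recovered
# peak parameters per region.
build_cohort_table <- function(truth, peaks) {
  out <- truth[, c("subject", "condition", "hr", "sv", "co")]
  for (rn in region_names()) {
    for (p in unique(peaks$parameter)) {
      col <- paste0(p, "_", rn)
      v <- merge(out[, c("subject", "condition")],
                 peaks[peaks$region == rn & peaks$parameter == p,
                       c("subject", "condition", "peak_value")],
                 by = c("subject", "condition"), sort = FALSE)
      out[[col]] <- v$peak_value[match(paste(out$subject, out$condition),
                                       paste(v$subject, v$condition))]
    }
  }
  out
}

#' Statistical layer on a cohort table
#'
#' Given a per-subject/condition cohort table (as produced by
#' [run_pipeline()], or read from CSV), computes paired rest-vs-stress
#' comparisons for every peak parameter and region, group-mean fold changes,
#' and linear regressions of peak total TKE on cardiac output, stroke
#' volume and heart rate with both conditions pooled.
#'
#' @param tab data frame with columns `subject`, `condition`, `hr`, `sv`,
#'   `co` and `<parameter>_<region>` peak columns.
#' @return nested list: `paired` (per parameter/region: test used, p-value,
#'   normality p, fold change of means), `regression` (per region and
#'   predictor: slope, `r_squared`, p-value).
#' @export
cohort_statistics <- function(tab) {
  stopifnot(all(c("subject", "condition") %in% names(tab)))
  rest <- tab[tab$condition == "rest", ]
  stress <- tab[tab$condition == "stress", ]
  stress <- stress[match(rest$subject, stress$subject), ]
  param_cols <- setdiff(names(tab),
                        c("subject", "condition", "hr", "sv", "co"))

  paired <- list()
  for (col in c("hr", "sv", "co", param_cols)) {
    pc <- if (nrow(rest) >= 3) {
      paired_compare(rest[[col]], stress[[col]])
    } else {
      # too few pairs for any test; report the descriptives only
      list(test_used = NA_character_, p_value = NA_real_,
           normality_p = NA_real_, degenerate = TRUE)
    }
    paired[[col]] <- list(
      test_used = pc$test_used, p_value = pc$p_value,
      normality_p = pc$normality_p, degenerate = pc$degenerate,
      rest_mean = mean(rest[[col]]), stress_mean = mean(stress[[col]]),
      fold = if (mean(rest[[col]]) > 0) {
        fold_change(mean(rest[[col]]), mean(stress[[col]]))
      } else NA_real_)
  }

  regression <- list()
  for (rn in region_names()) {
    ycol <- paste0("tke_total_", rn)
    if (!ycol %in% names(tab)) next
    for (xcol in c("co", "sv", "hr")) {
      fit <- linear_fit(tab[[xcol]], tab[[ycol]])
      regression[[paste(rn, xcol, sep = "_")]] <- list(
        region = rn, predictor = xcol, slope = fit$slope,
        intercept = fit$intercept, r_squared = fit$r_squared,
        p_value = fit$p_value, n = fit$n)
    }
  }
  list(paired = paired, regression = regression)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run: %d subjects x 2 conditions, seed %d\n",
              x$config$n_subjects, x$config$seed))
  tk <- x$stats$paired[["tke_total_TAo"]]
  if (!is.null(tk)) {
    cat(sprintf("  TAo peak TKE_total: %.2f -> %.2f mJ (fold %.1f, %s p=%.3g)\n",
                tk$rest_mean, tk$stress_mean, tk$fold, tk$test_used,
                tk$p_value))
  }
  rg <- x$stats$regression[["TAo_co"]]
  if (!is.null(rg)) {
    cat(sprintf("  peak TKE_total ~ CO (TAo): R^2 = %.2f, p = %.3g\n",
                rg$r_squared, rg$p_value))
  }
  cat(sprintf("  max |recovery error| of TAo peak TKE_total: %.3g\n",
              max(abs(x$recovery$rel_error))))
  invisible(x)
}
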