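#' End-to-end pipeline configuration
#'
#' One configuration object drives the whole analysis; all randomness flows
#' from `seed` through named per-stage sub-streams ([derive_seed()]), so a
#' rerun with the same configuration reproduces every deterministic output.
#'
#' @param out_dir directory for artifacts (created if missing).
#' @param n_per_class synthetic slides per class for the imaging stages.
#' @param texture_effect class texture separation in `[0, 1]`.
#' @param slide_px,tile_px slide and tile size in pixels (the default
#'   1024/128 gives the same 8 x 8 tile grid as full-scale 4096/512).
#' @param input_mode `"single"`, `"front-in"`, `"front-out"`,
#'   `"front-both"`, or `"stack:n"` (e.g. `"stack:4"`).
#' @param folds cross-validation folds.
#' @param classifier a [classifier_config()] (its seed is overridden by the
#'   pipeline seed).
#' @param smoothing_window median-filter window in tiles.
#' @param vote slide vote rule, `"mean"` or `"count"`.
#' @param cohort_n tumors per cohort for the statistics stages.
#' @param rfm_factors risk factors of the reported RFM.
#' @param stages which stages to run: subset of `"imaging"`,
#'   `"riskstats"`, `"survival"`.
#' @param n_heatmaps number of probability maps to render.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = file.path(tempdir(), "metrisk_run"),
                            n_per_class = c(non_met = 20, rapid_met = 20),
                            texture_effect = 1,
                            slide_px = 1024L, tile_px = 128L,
                            input_mode = "single", folds = 4L,
                            classifier = classifier_config(),
                            smoothing_window = 2L, vote = "mean",
                            cohort_n = c(non_met = 59, rapid_met = 22),
                            rfm_factors = c("ai_met", "clark5", "diam_ge30"),
                            stages = c("imaging", "riskstats", "survival"),
                            n_heatmaps = 2L, seed = 1L) {
  stopifnot(all(stages %in% c("imaging", "riskstats", "survival")))
  structure(list(out_dir = out_dir, n_per_class = n_per_class,
                 texture_effect = texture_effect, slide_px = as.integer(slide_px),
                 tile_px = as.integer(tile_px), input_mode = input_mode,
                 folds = as.integer(folds), classifier = classifier,
                 smoothing_window = as.integer(smoothing_window), vote = vote,
                 cohort_n = cohort_n, rfm_factors = rfm_factors,
                 stages = stages, n_heatmaps = as.integer(n_heatmaps),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full metastasis-risk pipeline
#'
#' Executes, per the configuration: synthetic slide generation, tiling and
#' featurization; patient-exclusive cross-validated training with
#' out-of-fold tile probabilities; score-grid smoothing, slide decisions,
#' ROC/AUROC, confusion summary and probability maps; the risk-factor
#' statistics (published-fixture reproduction plus RFMs on the synthetic
#' cohort); and Kaplan-Meier survival by risk-factor stratum. Artifacts
#' are written under `config$out_dir` together with a manifest listing
#' every file with its MD5 checksum and the seeds used.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `pipeline_result` (see elements in the details).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  files <- character(0)

  if ("imaging" %in% config$stages) {
    im <- tryCatch(run_imaging_stage(config),
                   error = function(e) stop("stage 'imaging' failed: ",
                                            conditionMessage(e), call. = FALSE))
    res <- c(res, im$result)
    files <- c(files, im$files)
  }
  if ("riskstats" %in% config$stages) {
    rs <- tryCatch(run_riskstats_stage(config),
                   error = function(e) stop("stage 'riskstats' failed: ",
                                            conditionMessage(e), call. = FALSE))
    res <- c(res, rs$result)
    files <- c(files, rs$files)
  }
  if ("survival" %in% config$stages) {
    if (is.null(res$cohort)) {
      rs <- run_riskstats_stage(config)
      res <- c(res, rs$result)
      files <- c(files, rs$files)
    }
    sv <- tryCatch(run_survival_stage(config, res$cohort, res$profiles),
                   error = function(e) stop("stage 'survival' failed: ",
                                            conditionMessage(e), call. = FALSE))
    res <- c(res, sv$result)
    files <- c(files, sv$files)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed,
         stage_seeds = list(slides = "derived per slide id",
                            folds = derive_seed(config$seed, "folds"),
                            train = derive_seed(config$seed, "train"),
                            cohort = derive_seed(config$seed, "cohort")),
         package_version = as.character(utils::packageVersion("metrisk")),
         stages = config$stages,
         files = manifest),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  structure(res, class = "pipeline_result")
}

run_imaging_stage <- function(config) {
  all_tiles <- list(); all_feats <- list()
  for (cohort in names(config$n_per_class)) {
    for (i in seq_len(config$n_per_class[[cohort]])) {
      sid <- sprintf("%s_s%03d", cohort, i)
      spec <- synthetic_slide_spec(
        slide_id = sid, cohort = cohort,
        width_px = config$slide_px, height_px = config$slide_px,
        texture_effect = config$texture_effect,
        seed = derive_seed(config$seed, paste0("slide_", sid)))
      sl <- generate_slide(spec)
      tiles <- extract_tiles(sl$rgb_image, sl$annotation_mask,
                             tile_px = config$tile_px, label = cohort,
                             slide_id = sid, patient_id = sid)
      front_mode <- grepl("^front", config$input_mode)
      if (front_mode) {
        side <- switch(config$input_mode, `front-in` = "inside",
                       `front-out` = "outside", `front-both` = "both")
        tiles <- select_invasive_front(tiles, side = side)
      }
      sf <- slide_tile_features(sl$rgb_image, tiles,
                                which = if (front_mode) "valid" else "valid_tumor")
      all_tiles[[sid]] <- sf$tiles
      all_feats[[sid]] <- sf$features
    }
  }
  tiles <- do.call(rbind, all_tiles)
  rownames(tiles) <- NULL
  features <- do.call(rbind, all_feats)
  if (nrow(tiles) == 0) stop("no valid tumor tiles were produced")

  tiles$cohort <- tiles$label
  folds <- assign_folds(tiles, k = config$folds,
                        seed = derive_seed(config$seed, "folds"))
  cfg <- config$classifier
  cfg$seed <- derive_seed(config$seed, "train")
  if (grepl("^stack:", config$input_mode)) {
    n_stack <- as.integer(sub("^stack:", "", config$input_mode))
    stacked <- make_tile_stacks(tiles, n = n_stack,
                                seed = derive_seed(config$seed, "stacks"))
    features <- features[match(paste(stacked$slide_id, stacked$row, stacked$col),
                               paste(tiles$slide_id, tiles$row, tiles$col)), ,
                         drop = FALSE]
    tiles <- stacked
  }
  cv <- train_cv(tiles, features, folds, cfg)

  n_grid <- config$slide_px %/% config$tile_px
  cells <- if (grepl("^front", config$input_mode)) "scored" else "valid_tumor"
  grids <- lapply(split(cv$oof, cv$oof$slide_id), function(s)
    median_smooth(score_grid(s, n_rows = n_grid, n_cols = n_grid, cells = cells),
                  window = config$smoothing_window))
  decisions <- do.call(rbind, lapply(names(grids), function(sid)
    slide_score(grids[[sid]],
                true_label = cv$oof$label[cv$oof$slide_id == sid][1],
                vote = config$vote)))
  rownames(decisions) <- NULL

  slide_roc <- roc_curve(decisions$mean_score, decisions$true_label != "non_met")
  tile_roc <- roc_curve(cv$oof$prob, cv$oof$label != "non_met")
  conf <- confusion_summary(decisions)

  f_oof <- file.path(config$out_dir, "oof_probabilities.csv")
  utils::write.csv(cv$oof[, c("slide_id", "row", "col", "fold", "prob", "label")],
                   f_oof, row.names = FALSE)
  f_dec <- file.path(config$out_dir, "slide_decisions.csv")
  utils::write.csv(decisions, f_dec, row.names = FALSE)
  f_roc <- file.path(config$out_dir, "slide_roc.csv")
  utils::write.csv(as.data.frame(slide_roc), f_roc, row.names = FALSE)
  files <- c(f_oof, f_dec, f_roc)
  for (sid in utils::head(names(grids), config$n_heatmaps)) {
    f <- file.path(config$out_dir, paste0("heatmap_", sid, ".png"))
    render_probability_map(grids[[sid]], file = f)
    files <- c(files, f)
  }

  list(result = list(tiles = tiles, cv = cv, grids = grids,
                     decisions = decisions,
                     slide_auroc = attr(slide_roc, "auroc"),
                     tile_auroc = attr(tile_roc, "auroc"),
                     confusion = conf),
       files = files)
}

run_riskstats_stage <- function(config) {
  cohort <- generate_cohort(config$cohort_n,
                            seed = derive_seed(config$seed, "cohort"))
  profiles <- risk_factor_profiles(cohort)
  rfm <- build_rfm(profiles, config$rfm_factors)
  fixtures <- load_paper_fixtures()
  fixture_report <- risk_table(fixtures$table2)
  aucs <- vapply(fixtures$table2, ordinal_auc, numeric(1))

  f_cohort <- file.path(config$out_dir, "cohort.csv")
  utils::write.csv(cohort, f_cohort, row.names = FALSE)
  f_risk <- file.path(config$out_dir, "risk_table_fixtures.csv")
  utils::write.csv(fixture_report, f_risk, row.names = FALSE)
  f_rfm <- file.path(config$out_dir, "rfm_synthetic.csv")
  utils::write.csv(data.frame(rf_count = rfm$levels, cases = rfm$cases,
                              controls = rfm$controls),
                   f_rfm, row.names = FALSE)

  list(result = list(cohort = cohort, profiles = profiles,
                     rfm_synthetic = rfm, rfm_auc = ordinal_auc(rfm),
                     fixture_report = fixture_report, fixture_auc = aucs),
       files = c(f_cohort, f_risk, f_rfm))
}

run_survival_stage <- function(config, cohort, profiles) {
  fm <- as.matrix(profiles[, config$rfm_factors, drop = FALSE])
  keep <- stats::complete.cases(fm)
  rf <- rowSums(fm[keep, , drop = FALSE])
  recs <- data.frame(tumor_id = cohort$tumor_id[keep],
                     stratum = paste0(rf, "_rf"),
                     time_days = cohort$dss_days[keep],
                     event = cohort$dss_event[keep])
  curves <- km_by_stratum(recs)
  five_year <- vapply(curves, survival_at, numeric(1), t_days = 1826)
  medians <- vapply(curves, function(cv) as.numeric(median_survival(cv)), numeric(1))

  f_surv <- file.path(config$out_dir, "km_dss_by_rf.csv")
  utils::write.csv(do.call(rbind, lapply(names(curves), function(s)
    data.frame(stratum = rep(s, length(curves[[s]]$time)),
               time = curves[[s]]$time, surv = curves[[s]]$surv))),
    f_surv, row.names = FALSE)

  list(result = list(km_dss = curves, dss_5y = five_year,
                     dss_median_days = medians),
       files = f_surv)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Metastasis-risk pipeline run\n")
  if (!is.null(x$slide_auroc))
    cat(sprintf("  slide AUROC %.3f | tile AUROC %.3f | sens %d%% spec %d%% acc %d%%\n",
                x$slide_auroc, x$tile_auroc, x$confusion$sensitivity_pct,
                x$confusion$specificity_pct, x$confusion$accuracy_pct))
  if (!is.null(x$rfm_auc))
    cat(sprintf("  synthetic-cohort RFM AUROC %.3f (factors: %s)\n",
                x$rfm_auc, paste(x$config$rfm_factors, collapse = ", ")))
  if (!is.null(x$dss_5y))
    cat(sprintf("  5-y DSS by RF stratum: %s\n",
                paste(sprintf("%s=%.2f", names(x$dss_5y), x$dss_5y), collapse = " ")))
  cat(sprintf("  artifacts: %s\n", x$config$out_dir))
  invisible(x)
}
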