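# End-to-end orchestration: simulate -> extract -> stats -> fit/score -> roc,
# with per-stage artifacts, provenance metadata and full seed control.

#' Pipeline run configuration
#'
#' @param out_dir directory for stage artifacts (`NULL` = keep in memory
#'   only).
#' @param n_samples_per_grade,nuclei_per_sample,pixel_size_um,image_size
#'   cohort shape, passed to [cohort_spec()].
#' @param seed root RNG seed.
#' @param alpha ANOVA screening significance level.
#' @param enter_p,remove_p stepwise entry/removal thresholds.
#' @param model `"fit"` to fit the stepwise discriminant on the simulated
#'   cohort, or `"paper"` to score with the published model.
#' @param candidates candidate features for the stepwise fit (default: all
#'   38 descriptors).
#' @param write_images also write TIFF scenes/masks (slow; default FALSE).
#' @return a `run_config` list, schema-checked.
#' @export
nm_config <- function(out_dir = NULL,
                      n_samples_per_grade = c(G13 = 24, G4 = 20, G5 = 16),
                      nuclei_per_sample = 100,
                      pixel_size_um = 0.25,
                      image_size = NULL,
                      seed = 1,
                      alpha = 0.05,
                      enter_p = 0.05,
                      remove_p = 0.10,
                      model = c("fit", "paper"),
                      candidates = feature_names(),
                      write_images = FALSE) {
  model <- match.arg(model)
  cfg <- list(out_dir = out_dir,
              n_samples_per_grade = n_samples_per_grade,
              nuclei_per_sample = nuclei_per_sample,
              pixel_size_um = pixel_size_um,
              image_size = image_size,
              seed = seed, alpha = alpha,
              enter_p = enter_p, remove_p = remove_p,
              model = model, candidates = candidates,
              write_images = write_images)
  # schema check before any compute
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$enter_p > 0, cfg$remove_p >= cfg$enter_p,
            is.character(cfg$candidates), length(cfg$candidates) >= 1)
  class(cfg) <- "run_config"
  cfg
}

write_stage_csv <- function(df, cfg, name) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> extract -> aggregate -> ANOVA screen -> discriminant
#' fit (or published-model scoring) -> ROC with Youden-optimal cutoff, and
#' classifies every sample as low grade (Gleason <= 3) or high grade
#' (Gleason >= 4). All randomness derives from `config$seed`; rerunning an
#' identical configuration reproduces every artifact.
#'
#' @param config a [nm_config()].
#' @return list of class `nm_run` with the cohort, feature table, sample
#'   records, ANOVA screen, chromatin summary, fitted/loaded model, scores,
#'   ROC, chosen cutoff, per-sample classification and a `provenance` record.
#' @export
run_pipeline <- function(config = nm_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  spec <- cohort_spec(config$n_samples_per_grade, config$nuclei_per_sample,
                      seed = config$seed, image_size = config$image_size,
                      pixel_size_um = config$pixel_size_um)
  cohort <- generate_cohort(spec)
  if (isTRUE(config$write_images) && !is.null(config$out_dir)) {
    write_cohort(cohort, file.path(config$out_dir, "scenes"))
  }
  features <- extract_table(cohort)
  write_stage_csv(features, config, "features.csv")
  records <- aggregate_samples(features)
  write_stage_csv(records, config, "samples.csv")
  screen <- anova_screen(records, alpha = config$alpha)
  write_stage_csv(screen, config, "anova.csv")
  chromatin <- chromatin_summary(records)
  write_stage_csv(chromatin, config, "chromatin.csv")

  if (config$model == "paper") {
    model <- paper_model()
  } else {
    model <- fit_stepwise(records, config$candidates,
                          enter_p = config$enter_p,
                          remove_p = config$remove_p)
  }
  scores <- ds_score(records, model)
  cls <- factor(ifelse(records$grade_group == "G13", "low", "high"),
                levels = c("low", "high"))
  roc <- roc_curve(scores, cls, positive = "high")
  cut <- pick_cutoff(roc)
  fitted_model <- nm_discriminant(model$intercept, model$coefficients,
                                  cutoff = cut$cutoff)
  calls <- classify_ds(scores, fitted_model)
  score_tab <- data.frame(sample_id = records$sample_id,
                          grade_group = records$grade_group,
                          score = scores, call = calls)
  write_stage_csv(score_tab, config, "scores.csv")

  prov <- list(package_version = as.character(utils::packageVersion("nucmorph")),
               seed = config$seed,
               n_samples_per_grade = as.list(config$n_samples_per_grade),
               nuclei_per_sample = config$nuclei_per_sample,
               pixel_size_um = config$pixel_size_um,
               alpha = config$alpha, model = config$model,
               started = format(t0), finished = format(Sys.time()))
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(config = config, cohort = cohort, features = features,
                 records = records, screen = screen, chromatin = chromatin,
                 model = fitted_model, scores = score_tab, roc = roc,
                 cutoff = cut, provenance = prov),
            class = "nm_run")
}

#' @export
print.nm_run <- function(x, ...) {
  cat(sprintf(paste0("<nm_run> %d samples, %d nuclei measured\n",
                     "  significant features: %d/%d\n",
                     "  discriminant: %s (%d features)\n",
                     "  AUC %.4f; cutoff %.4f -> sens %.1f%%, spec %.1f%%\n"),
              nrow(x$records), nrow(x$features),
              sum(x$screen$significant), nrow(x$screen),
              x$config$model, length(x$model$coefficients),
              x$roc$auc, x$cutoff$cutoff,
              100 * x$cutoff$sensitivity, 100 * x$cutoff$specificity))
  invisible(x)
}

#' Serialize / read a discriminant model as JSON
#'
#' @param model an `nm_discriminant`.
#' @param path JSON file path.
#' @return `write_model`: the path, invisibly. `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "nm_discriminant"))
  jsonlite::write_json(list(intercept = model$intercept,
                            coefficients = as.list(model$coefficients),
                            cutoff = model$cutoff,
                            orientation = model$orientation),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm_discriminant(x$intercept, unlist(x$coefficients), x$cutoff,
                  x$orientation)
}
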