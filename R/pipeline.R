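#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the data source
#' (a [phantom_config()] or a directory of volumes + masks + `cohort.csv`),
#' preprocessing, the ICC threshold, harmonization mode, the model roster
#' and the seeds. All stochastic stages (cohort generation, CV folds,
#' bootstrap) derive their seeds from `seed`.
#'
#' @param data a [phantom_config()] or a directory path written by
#'   [write_cohort()].
#' @param spacing,bin_width,lbp_radius preprocessing settings.
#' @param icc_threshold feature retention threshold (default 0.8).
#' @param combat `"joint"` (fit on train+test, the default), `"train"`
#'   (fit on training only) or `"off"`.
#' @param models radiomic model roster (feature classes per model).
#' @param bootstrap_B bootstrap replicates for AUC CIs.
#' @param seed master seed.
#' @param out_dir optional output directory; when given, all artifacts are
#'   written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data = phantom_config(),
                            spacing = 1, bin_width = 5, lbp_radius = 1,
                            icc_threshold = 0.8,
                            combat = c("joint", "train", "off"),
                            models = list(
                              "Radiomics-texture" = "texture",
                              "Radiomics-shape" = "shape",
                              "Radiomics-intensity" = "intensity",
                              "Radiomics-LBP" = "lbp",
                              "Radiomics-combined" = c("texture", "shape",
                                                       "intensity", "lbp")),
                            bootstrap_B = 1000,
                            seed = 1,
                            out_dir = NULL) {
  combat <- match.arg(combat)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow: cohort generation (or loading),
#' feature extraction for both raters, ICC robustness filtering on the
#' training rater-paired subset, batch harmonization, LASSO model fitting
#' with 10-fold CV on the training cohort, conventional baselines, and
#' held-out evaluation (bootstrap ROC, confusion metrics at the training
#' maxstat cutpoint, calibration, decision curves). All data-dependent
#' choices (retained features, lambda, cutpoints) are frozen on the
#' training cohort before the test cohort is scored.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_result` list: `features` (harmonized feature table),
#'   `robustness`, `retained`, `combat`, `models`, `evaluation` (per-model
#'   tibble), and the per-model detail objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (inherits(config$data, "phantom_config")) {
    generate_cohort(config$data)
  } else {
    read_cohort(config$data)
  }
  stage <- function(lbl, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", lbl, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }
  feats <- stage("extract", extract_features(
    cohort, spacing = config$spacing, bin_width = config$bin_width,
    lbp_radius = config$lbp_radius))
  # robustness on the training rater-paired subset only
  paired_idx <- which(cohort$cohort == "train" &
                        !purrr::map_lgl(cohort$mask_rater2, is.null))
  rob <- NULL
  retained <- feature_panel()
  if (length(paired_idx) >= 2) {
    feats2 <- stage("extract-rater2", extract_features(
      cohort[paired_idx, ], mask_col = "mask_rater2", spacing = config$spacing,
      bin_width = config$bin_width, lbp_radius = config$lbp_radius))
    rob <- stage("robustness", feature_robustness(
      feats[match(feats2$node_id, feats$node_id), ], feats2,
      threshold = config$icc_threshold))
    retained <- rob$feature[rob$retained]
  }
  cb <- NULL
  if (config$combat != "off") {
    fit_rows <- if (config$combat == "joint") seq_len(nrow(feats)) else
      which(feats$cohort == "train")
    cb <- stage("harmonize", combat_fit(feats[fit_rows, ], feats$batch[fit_rows]))
    feats <- stage("harmonize", combat_apply(feats, cb, feats$batch))
  }
  train <- feats[feats$cohort == "train", ]
  test <- feats[feats$cohort == "test", ]
  cls <- feature_class(retained)
  models <- list()
  for (nm in names(config$models)) {
    fset <- retained[cls %in% config$models[[nm]]]
    if (length(fset) == 0) {
      rlang::warn(paste0("model '", nm, "' skipped: no retained features ",
                         "in its class(es)."))
      next
    }
    m <- stage(nm, fit_lasso(train, fset, seed = config$seed, name = nm))
    models[[nm]] <- stage(nm, set_cutpoint(m, train))
  }
  conventional <- list(
    "LN short diameter" = "short_diameter_mm",
    "LN volume" = "volume_cm3",
    "Expert rating" = "expert_rating",
    "SUVmax" = "suvmax")
  for (nm in names(conventional)) {
    cov <- conventional[[nm]]
    if (!cov %in% names(train)) next
    m <- stage(nm, fit_conventional(train, cov, name = nm))
    models[[nm]] <- stage(nm, set_cutpoint(m, train))
  }
  evaluation <- purrr::imap_dfr(models, function(m, nm) {
    ev_tr <- evaluate_model(m, train, B = config$bootstrap_B,
                            seed = config$seed)
    ev_te <- evaluate_model(m, test, B = config$bootstrap_B,
                            seed = config$seed)
    tibble::tibble(model = nm,
                   auc_train = ev_tr$roc$auc,
                   auc_train_lo = ev_tr$roc$ci[1],
                   auc_train_hi = ev_tr$roc$ci[2],
                   auc_test = ev_te$roc$auc,
                   auc_test_lo = ev_te$roc$ci[1],
                   auc_test_hi = ev_te$roc$ci[2],
                   mcc = ev_te$confusion$mcc,
                   balanced_accuracy = ev_te$confusion$balanced_accuracy,
                   sensitivity = ev_te$confusion$sensitivity,
                   specificity = ev_te$confusion$specificity,
                   ppv = ev_te$confusion$ppv,
                   npv = ev_te$confusion$npv)
  })
  details <- purrr::map(models, function(m) {
    list(test = evaluate_model(m, test, B = config$bootstrap_B,
                               seed = config$seed))
  })
  res <- structure(list(config = config, cohort_meta = dplyr::select(
    cohort, -dplyr::any_of(c("image", "mask_rater1", "mask_rater2"))),
    features = feats, robustness = rob, retained = retained,
    combat = cb, models = models, evaluation = evaluation,
    details = details), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' Evaluate a fitted model on a cohort
#'
#' @param model an `lnm_model` with a cutpoint set.
#' @param data feature table of the cohort to score.
#' @param y_col outcome column.
#' @param B,seed bootstrap control.
#' @return list with `roc` (`lnm_roc`), `confusion`, `calibration`,
#'   `decision_curve` and the scores.
#' @export
evaluate_model <- function(model, data, y_col = "label", B = 1000, seed = 1) {
  sc <- predict(model, data, type = "link")
  pr <- stats::plogis(sc)
  y <- data[[y_col]]
  pred <- if (!is.null(model$cutpoint)) as.integer(sc >= model$cutpoint) else
    as.integer(pr >= 0.5)
  list(roc = bootstrap_auc_ci(sc, y, B = B, seed = seed),
       confusion = confusion_metrics(pred, y),
       calibration = calibration_curve(pr, y),
       decision_curve = decision_curve(pr, y),
       scores = sc, probabilities = pr, y = y)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory with per-node image/mask files and `cohort.csv`.
#' @return a cohort tibble (as [generate_cohort()]).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort.csv")
  if (!file.exists(meta_path)) {
    rlang::abort("cohort.csv not found.", class = "lnrad_io_error")
  }
  meta <- tibble::as_tibble(utils::read.csv(meta_path))
  find1 <- function(id, suffix) {
    hits <- Sys.glob(file.path(dir, paste0(id, "_", suffix, ".*")))
    if (length(hits) == 0) NULL else hits[1]
  }
  meta$image <- purrr::map(meta$node_id, ~ read_volume(find1(.x, "image")))
  meta$mask_rater1 <- purrr::map(meta$node_id, ~ read_mask(find1(.x, "mask")))
  meta$mask_rater2 <- purrr::map(meta$node_id, function(id) {
    p <- find1(id, "mask_rater2")
    if (is.null(p)) NULL else read_mask(p)
  })
  meta
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(res$robustness)) {
    utils::write.csv(res$robustness, file.path(dir, "robustness.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$evaluation, file.path(dir, "evaluation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(feature_manifest(res$config$spacing,
                                        res$config$bin_width,
                                        res$config$lbp_radius),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  models_json <- purrr::map(res$models, function(m) {
    list(name = m$name, type = m$type, intercept = unname(m$intercept),
         coefficients = as.list(m$beta), lambda = m$lambda,
         cutpoint = m$cutpoint)
  })
  jsonlite::write_json(models_json, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d nodes (%d train / %d test), %d features, %d retained\n",
              nrow(x$features), sum(x$features$cohort == "train"),
              sum(x$features$cohort == "test"),
              length(feature_panel()), length(x$retained)))
  print(dplyr::select(x$evaluation, "model", "auc_train", "auc_test",
                      "mcc", "balanced_accuracy"))
  invisible(x)
}
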