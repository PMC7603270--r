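#' End-to-end pipeline orchestration
#'
#' `run_training()` takes a cohort (simulated in memory or read from a
#' fixture directory) through enrichment scoring, phenotype clustering,
#' radiomic extraction, the three-stage feature filter, per-subset
#' logistic modelling with LOOCV and a survival comparison of the
#' phenotype groups. `run_inference()` applies trained models to a new
#' cohort and compares the survival of the predicted groups.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param modalities modalities to train on (`"t1c"`, `"adc"` or both;
#'   default `"t1c"`, the better-performing sequence).
#' @param weight GSEA weighting exponent.
#' @param center_genes rank samples on cohort-median-centered log
#'   expression when scoring enrichment (default TRUE; see
#'   [center_expression()]).
#' @param n_permutations permutation-null size for NES.
#' @param radiomics a [radiomics_config()].
#' @param stage1_threshold,min_abs,strategy feature-filter settings.
#' @param ridge logistic ridge stabilizer.
#' @param max_model_features cap on predictors per subset model, taken
#'   from the top of stage 3's descending-gain ranking (default 12, the
#'   order of the model sizes reported for this methodology; `Inf`
#'   disables the cap).
#' @param seed master seed for scoring, filtering and models.
#' @return a `run_config` list.
#' @export
run_config <- function(modalities = "t1c", weight = 1, center_genes = TRUE,
                       n_permutations = 1000,
                       radiomics = radiomics_config(),
                       stage1_threshold = 0.90, min_abs = 0.2,
                       strategy = "per_set_median", ridge = 1e-6,
                       max_model_features = 12, seed = 1L) {
  structure(list(modalities = modalities, weight = weight,
                 center_genes = center_genes,
                 n_permutations = n_permutations, radiomics = radiomics,
                 stage1_threshold = stage1_threshold, min_abs = min_abs,
                 strategy = strategy, ridge = ridge,
                 max_model_features = max_model_features,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Train the radiomic immunophenotyping models on a cohort
#'
#' @param cohort a [simulate_cohort()] result or [read_fixtures()] list
#'   (expression on both platforms, volumes + masks, clinical table).
#' @param config a [run_config()].
#' @return a `training_run`: enrichment profiles, cluster labels, filter
#'   report, per-modality subset models and LOOCV results, survival
#'   comparison of the clustered groups, and a manifest.
#' @export
run_training <- function(cohort, config = run_config()) {
  log_expr <- stage_wrap("expression", log_fpkm(cohort$expression$rnaseq))
  array_norm <- stage_wrap("expression",
                           normalize_array(cohort$expression$microarray))
  score_input <- if (isTRUE(config$center_genes %||% TRUE))
    center_expression(log_expr) else log_expr
  nes_mat <- stage_wrap("enrichment",
    score_cohort(score_input, cohort$catalog, weight = config$weight,
                 n_permutations = config$n_permutations, seed = config$seed))
  profiles <- stage_wrap("enrichment", enrichment_profiles(nes_mat))
  levels <- binarize_levels(nes_mat)

  clusters <- stage_wrap("immunophenotyping",
                         cluster_profiles(nes_mat, k = 5, seed = config$seed))
  labels <- stage_wrap("immunophenotyping", label_clusters(clusters, levels))
  rule_groups <- map_levels_to_group(levels)

  per_modality <- list()
  for (mod in config$modalities) {
    feats <- stage_wrap("radiomics",
      extract_cohort(cohort$volumes, mod, config$radiomics,
                     spacing = cohort$spacing))
    report <- stage_wrap("feature_selection",
      select_features(feats, log_expr, array_norm, cohort$catalog, levels,
                      seed = config$seed,
                      stage1_threshold = config$stage1_threshold,
                      min_abs = config$min_abs, strategy = config$strategy))
    models <- list()
    cv <- list()
    for (s in SUBSETS) {
      sel <- utils::head(report$selected[[s]],
                         config$max_model_features %||% Inf)
      if (length(sel) == 0) {
        warning("no features selected for ", s, " (", mod, ")")
        next
      }
      models[[s]] <- stage_wrap("modeling",
        fit_subset_model(feats[, sel, drop = FALSE], levels[, s], s,
                         ridge = config$ridge))
      cv[[s]] <- stage_wrap("modeling",
        loocv(feats[, sel, drop = FALSE], levels[, s], s,
              ridge = config$ridge))
    }
    per_modality[[mod]] <- list(features = feats, report = report,
                                models = models, loocv = cv)
  }

  surv_records <- stage_wrap("survival", {
    cl <- idh_filter(cohort$clinical)
    merge(cl, data.frame(sample_id = labels$sample_id, group = labels$group),
          by = "sample_id")
  })
  km <- lapply(split(surv_records, surv_records$group), function(d)
    km_estimate(d$survival_days, d$event))
  lr <- stage_wrap("survival", pairwise_logrank(surv_records))

  manifest <- list(
    seed = config$seed,
    n_samples = nrow(nes_mat),
    modalities = config$modalities,
    counts = lapply(per_modality, function(m) as.list(m$report$counts)),
    selected = lapply(per_modality, function(m)
      lapply(m$report$selected, length)),
    group_sizes = as.list(table(labels$group)))

  structure(list(nes = nes_mat, profiles = profiles, levels = levels,
                 clusters = clusters, labels = labels,
                 rule_groups = rule_groups,
                 modalities = per_modality,
                 survival = list(records = surv_records, km = km,
                                 logrank = lr),
                 manifest = manifest, config = config),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat("<training_run>\n")
  cat("  n =", x$manifest$n_samples, "\n")
  cat("  groups:", paste(names(x$manifest$group_sizes),
                         unlist(x$manifest$group_sizes), collapse = ", "),
      "\n")
  for (mod in names(x$modalities)) {
    cv <- x$modalities[[mod]]$loocv
    accs <- vapply(cv, function(r) r$accuracy, numeric(1))
    cat(sprintf("  %s LOOCV accuracy: %s\n", mod,
                paste(sprintf("%s=%.2f", names(accs), accs), collapse = " ")))
  }
  invisible(x)
}

#' Predict phenotype groups for a new cohort and compare their survival
#'
#' Only the features required by the four models are extracted, then
#' predicted enrichment levels are mapped to groups and the predicted
#' groups' survival is compared with KM curves and pairwise log-rank
#' tests (IDH wild-type patients only).
#'
#' @param models named list of four `subset_model`s (e.g.
#'   `run$modalities$t1c$models`).
#' @param cohort a cohort list with `volumes`, `spacing`, `clinical`.
#' @param modality modality the models were trained on.
#' @param config a [run_config()] (radiomics settings are reused; the
#'   feature list is restricted automatically).
#' @return an `inference_run`: predictions, predicted-group counts, KM
#'   curves and pairwise log-rank results.
#' @export
run_inference <- function(models, cohort, modality = "t1c",
                          config = run_config()) {
  need <- unique(unlist(lapply(models, `[[`, "features")))
  rc <- config$radiomics
  rc$features <- need
  feats <- stage_wrap("radiomics",
    extract_cohort(cohort$volumes, modality, rc, spacing = cohort$spacing))
  preds <- stage_wrap("modeling", predict_groups(models, feats))
  counts <- table(factor(preds$group, levels = PHENOTYPE_GROUPS))
  cl <- idh_filter(cohort$clinical)
  rec <- merge(cl, preds[, c("sample_id", "group")], by = "sample_id")
  rec <- rec[!is.na(rec$group), , drop = FALSE]
  km <- lapply(split(rec, rec$group), function(d)
    if (nrow(d)) km_estimate(d$survival_days, d$event) else NULL)
  lr <- if (length(unique(rec$group)) >= 2)
    pairwise_logrank(rec) else NULL
  structure(list(predictions = preds, group_counts = counts,
                 survival = list(records = rec, km = km, logrank = lr)),
            class = "inference_run")
}

#' Write the artifacts of a training run to a directory
#'
#' Emits open-format artifacts: IGS/radar CSV, labels CSV, filter ledger
#' + JSON, model JSON, LOOCV CSV, KM curves CSV, log-rank JSON and a
#' reproducibility manifest JSON.
#'
#' @param run a `training_run`.
#' @param dir output directory.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_igs_csv(run$profiles, file.path(dir, "immunogram.csv"))
  write_labels_csv(run$labels, file.path(dir, "labels.csv"))
  for (mod in names(run$modalities)) {
    m <- run$modalities[[mod]]
    mdir <- file.path(dir, mod)
    write_filter_report(m$report, mdir)
    write_models_json(m$models, file.path(mdir, "models.json"))
    cvdf <- do.call(rbind, lapply(m$loocv, function(r)
      data.frame(subset = r$subset, accuracy = r$accuracy, auc = r$auc)))
    write.csv(cvdf, file.path(mdir, "loocv.csv"), row.names = FALSE)
  }
  write_km_csv(run$survival$records, file.path(dir, "km_curves.csv"))
  jsonlite::write_json(run$survival$logrank, file.path(dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
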