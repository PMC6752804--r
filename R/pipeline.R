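# End-to-end orchestration: simulate -> cohort -> featurize -> train ->
# test, reproducible from one seed, with JSON/text report artifacts.

#' Pipeline run configuration
#'
#' Collects every tunable of a full run with documented defaults.  The
#' configuration is a plain list and serialises round-trip stably via
#' [jsonlite::toJSON()] of `unclass(config)`.
#'
#' @param seed Integer master seed; every random draw in the run derives
#'   from it.
#' @param params Generator parameters ([cohort_params()]); its own `seed`
#'   field is overridden from `seed`.
#' @param representation Feature representations to run
#'   (`"signature"`, `"log_signature"`, or both).
#' @param train_window,test_window Month windows `c(start, end)`.
#' @param train_min_points,test_min_points Minimum complete visits.
#' @param folds Cross-validation folds.
#' @param age_tolerance Matching tolerance in years.
#' @param out_dir Optional directory for `report.json` and `tables.txt`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, params = cohort_params(),
                       representation = c("signature", "log_signature"),
                       train_window = c(0, 24), train_min_points = 4L,
                       test_window = c(12, 36), test_min_points = 3L,
                       folds = 10L, age_tolerance = 5, out_dir = NULL) {
  representation <- match.arg(representation, several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), params = params,
         representation = representation,
         train_window = train_window, train_min_points = train_min_points,
         test_window = test_window, test_min_points = test_min_points,
         folds = as.integer(folds), age_tolerance = age_tolerance,
         out_dir = out_dir),
    class = "run_config"
  )
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}

task_sets <- function(triples, role) {
  vapply(triples, `[[`, character(1), role)
}

#' Run the full classification pipeline
#'
#' Simulates disjoint training and test cohorts, applies the cohort
#' filters and age matching, builds feature vectors, and for each task
#' (AD vs NL, AD vs MCI) and each requested representation runs
#' cross-validated Lasso logistic regression, reports the features
#' selected at `lambda_1se`, picks the ROC threshold on the training
#' scores, and evaluates the confusion matrix on the held-out test
#' subjects.  Deterministic given `config$seed`; any stage failure aborts
#' with the stage name.
#'
#' @param config A [run_config()].
#' @return An object of class `pathsig_report`: per-representation,
#'   per-task selected features (min and 1se), CV curves, thresholds,
#'   confusion matrices and per-subject predictions, plus cohort
#'   bookkeeping.  Written to `config$out_dir` as `report.json` and
#'   `tables.txt` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  prm_tr <- config$params; prm_tr$seed <- derive_seed(config$seed, 1L)
  prm_te <- config$params; prm_te$seed <- derive_seed(config$seed, 2L)
  sim_tr <- stage("simulate-train",
                  generate_cohort(prm_tr, "training", id_prefix = "TR"))
  sim_te <- stage("simulate-test",
                  generate_cohort(prm_te, "test", id_prefix = "TE"))

  train_sets <- stage("cohort-train", build_training_sets(
    sim_tr$records, conversion_month = sim_tr$conversion_month,
    stability_months = 72,
    start_month = config$train_window[1L], end_month = config$train_window[2L],
    min_points = config$train_min_points, age_tolerance = config$age_tolerance))
  if (length(train_sets$triples) == 0L)
    stop("pipeline stage 'cohort-train' failed: no matched triples",
         call. = FALSE)
  test_sets <- stage("cohort-test", build_test_sets(
    sim_te$records, train_ids = names(sim_tr$records),
    conversion_month = sim_te$conversion_month, stability_months = 84,
    start_month = config$test_window[1L], end_month = config$test_window[2L],
    min_points = config$test_min_points))

  ad_ids <- task_sets(train_sets$triples, "ad")
  ctrl_ids <- list(AD_vs_NL = task_sets(train_sets$triples, "nl"),
                   AD_vs_MCI = task_sets(train_sets$triples, "mci"))
  ctrl_group <- c(AD_vs_NL = "stable_NL", AD_vs_MCI = "stable_MCI")
  ctrl_label <- c(AD_vs_NL = "NL", AD_vs_MCI = "MCI")

  results <- list()
  offset <- 10L
  for (rep_kind in config$representation) {
    feat_tr <- stage("featurize-train", featurize_records(
      sim_tr$records, config$train_window[1L], config$train_window[2L],
      config$train_min_points, TRUE, rep_kind))
    feat_te <- stage("featurize-test", featurize_records(
      test_sets$records, config$test_window[1L], config$test_window[2L],
      config$test_min_points, TRUE, rep_kind))
    for (task in names(ctrl_ids)) {
      offset <- offset + 1L
      ids_tr <- c(ad_ids, ctrl_ids[[task]])
      x_tr <- feat_tr$x[ids_tr, , drop = FALSE]
      y_tr <- as.integer(seq_along(ids_tr) <= length(ad_ids))
      te_keep <- names(test_sets$groups)[test_sets$groups %in%
                                           c("converter", ctrl_group[[task]])]
      te_keep <- intersect(te_keep, rownames(feat_te$x))
      x_te <- feat_te$x[te_keep, , drop = FALSE]
      y_te <- as.integer(test_sets$groups[te_keep] == "converter")
      cv <- stage(paste0("train-", task), cross_validate(
        x_tr, y_tr, folds = config$folds,
        seed = derive_seed(config$seed, offset)))
      train_scores <- predict(cv$fit, x_tr, cv$index_1se, type = "response")
      threshold <- suppressWarnings(choose_threshold(train_scores, y_tr))
      cm <- stage(paste0("test-", task), evaluate(
        cv, threshold, x_te, y_te, labels = c("AD", ctrl_label[[task]])))
      test_scores <- predict(cv$fit, x_te, cv$index_1se, type = "response")
      results[[rep_kind]][[task]] <- list(
        n_train = length(ids_tr), n_test = length(te_keep),
        lambda_min = cv$lambda_min, lambda_1se = cv$lambda_1se,
        cv_deviance = cv$cv_deviance, cv_se = cv$cv_se, lambdas = cv$lambdas,
        selected_min = selected_features(cv, "min"),
        selected_1se = selected_features(cv, "1se"),
        threshold = threshold, confusion = cm,
        balanced_accuracy = cm$balanced_accuracy,
        predictions = data.frame(subject_id = te_keep,
                                 score = unname(test_scores),
                                 actual = y_te,
                                 predicted = as.integer(test_scores > threshold),
                                 stringsAsFactors = FALSE)
      )
    }
  }
  report <- structure(
    list(config_seed = config$seed, representation = config$representation,
         n_triples = length(train_sets$triples),
         triples = train_sets$triples,
         train_window_rejections = train_sets$window_rejections,
         test_groups = test_sets$groups,
         test_window_rejections = test_sets$window_rejections,
         results = results),
    class = "pathsig_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

format_confusion <- function(cm) {
  lines <- c("            Predicted",
             sprintf("%18s %6s %6s %8s", cm$labels[1L], cm$labels[2L],
                     "Total", "Accuracy"))
  for (i in 1:2) {
    lines <- c(lines, sprintf("Actual %-6s %5d %6d %6d %8.2f", cm$labels[i],
                              cm$counts[i, 1L], cm$counts[i, 2L],
                              sum(cm$counts[i, ]), cm$per_class_accuracy[i]))
  }
  lines
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine-readable) and `tables.txt` (selected
#' feature lists and confusion matrices rendered as text tables).  Output
#' is byte-identical across runs with the same config.
#'
#' @param report A `pathsig_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ser <- report
  for (rk in names(ser$results)) {
    for (tk in names(ser$results[[rk]])) {
      cm <- ser$results[[rk]][[tk]]$confusion
      ser$results[[rk]][[tk]]$confusion <- list(
        labels = cm$labels, counts = unclass(cm$counts),
        per_class_accuracy = unname(cm$per_class_accuracy),
        balanced_accuracy = cm$balanced_accuracy)
    }
  }
  jsonlite::write_json(unclass(ser), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  lines <- character(0)
  for (rk in names(report$results)) {
    for (tk in names(report$results[[rk]])) {
      res <- report$results[[rk]][[tk]]
      lines <- c(lines, sprintf("== %s / %s ==", rk, tk),
                 "Selected at lambda_1se:",
                 if (nrow(res$selected_1se))
                   sprintf("  %-28s %+.4f", res$selected_1se$name,
                           res$selected_1se$coefficient)
                 else "  (none)",
                 format_confusion(res$confusion), "")
    }
  }
  writeLines(lines, file.path(out_dir, "tables.txt"))
  invisible(out_dir)
}

#' @export
print.pathsig_report <- function(x, ...) {
  cat(sprintf("<pathsig_report> seed %d, %d matched triples\n",
              x$config_seed, x$n_triples))
  for (rk in names(x$results)) {
    for (tk in names(x$results[[rk]])) {
      res <- x$results[[rk]][[tk]]
      cat(sprintf("%s / %s: lambda_1se %.4g; selected [%s]; balanced accuracy %.2f\n",
                  rk, tk, res$lambda_1se,
                  paste(res$selected_1se$name, collapse = ", "),
                  res$balanced_accuracy))
    }
  }
  invisible(x)
}
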