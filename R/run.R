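#' End-to-end run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param sessions_path Optional sessions JSONL to read; `NULL` generates a
#'   synthetic cohort from `spec`.
#' @param cohort_path Optional cohort metadata CSV (required with
#'   `sessions_path`).
#' @param spec A [cohort_spec()] used when no sessions file is given.
#' @param filter A [filter_config()].
#' @param pipeline A [pipeline_config()].
#' @param cutoff PHQ-9 group cutoff (default 5).
#' @param n_boot Bootstrap replicates for the ROC analysis (default 1000).
#' @param tolerance Convergence tolerance (default 0.05).
#' @param seed Master seed, propagated to every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, sessions_path = NULL, cohort_path = NULL,
                       spec = cohort_spec(), filter = filter_config(),
                       pipeline = pipeline_config(), cutoff = 5,
                       n_boot = 1000, tolerance = 0.05, seed = 1) {
  structure(list(out_dir = out_dir, sessions_path = sessions_path,
                 cohort_path = cohort_path, spec = spec, filter = filter,
                 pipeline = pipeline, cutoff = cutoff, n_boot = n_boot,
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening pipeline end to end
#'
#' Extraction, feature assembly, labelling, LOSO classification, bootstrap
#' ROC evaluation and convergence analysis, writing a feature table CSV, a
#' result JSON, a report JSON and a human-readable summary into the output
#' directory. Every random draw is controlled by the config seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory `features`, `labels`,
#'   `loso`, `roc`, `convergence` and the output paths.
#' @export
run_end_to_end <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$pipeline$seed <- cfg$seed
  if (is.null(cfg$sessions_path)) {
    cohort <- stage("simulate", generate_cohort(cfg$spec, seed = cfg$seed))
    sessions <- cohort$sessions
    subjects <- cohort$subjects
  } else {
    sessions <- stage("read", read_sessions(cfg$sessions_path, "jsonl"))
    subjects <- stage("read", read_cohort(cfg$cohort_path))
  }
  features <- stage("features", extract_features(sessions, cfg$filter))
  if (nrow(features) == 0) {
    stop("stage 'features' failed: zero valid sessions (",
         attr(features, "counts")["invalid"], " below the ",
         cfg$filter$min_keys, "-key validity minimum)", call. = FALSE)
  }
  message("features: ", paste(names(attr(features, "counts")),
                              attr(features, "counts"),
                              sep = "=", collapse = " "))
  labels <- stage("labels", cohort_labels(subjects, cfg$cutoff))
  loso <- stage("loso", run_loso(features, labels, cfg$pipeline))
  scores <- tibble::tibble(subject_id = loso$subjects$subject_id,
                           prob = loso$subjects$mean_prob,
                           label = loso$subjects$label)
  roc <- stage("evaluate",
               bootstrap_roc(scores, n_boot = cfg$n_boot, seed = cfg$seed))
  conv <- stage("convergence", convergence_report(loso, cfg$tolerance))
  sel <- selection_frequency_report(loso)

  paths <- list(
    features = file.path(cfg$out_dir, "features.csv"),
    result = file.path(cfg$out_dir, "loso_result.json"),
    report = file.path(cfg$out_dir, "report.json"),
    summary = file.path(cfg$out_dir, "summary.txt"))
  write_features(features, paths$features)
  jsonlite::write_json(loso_result_to_list(loso), paths$result,
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(
    auc_point = roc$auc_point, mean_auc = roc$mean_auc,
    ci = c(roc$ci_low, roc$ci_high),
    youden = list(threshold = roc$threshold,
                  sensitivity = roc$sensitivity,
                  specificity = roc$specificity),
    selection_frequency = sel,
    convergence = conv), paths$report, auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("subjects: %d (%d DT / %d HC), sessions with features: %d",
            nrow(loso$subjects), sum(loso$subjects$label == "DT"),
            sum(loso$subjects$label == "HC"), nrow(features)),
    sprintf("subject-level AUC: %.3f (bootstrap mean %.3f [%.3f-%.3f])",
            roc$auc_point, roc$mean_auc, roc$ci_low, roc$ci_high),
    sprintf("Youden threshold %.3f: sensitivity %.2f / specificity %.2f",
            roc$threshold, roc$sensitivity, roc$specificity),
    sprintf("median convergence: %d sessions", round(median(conv$n_converge)))),
    paths$summary)
  invisible(list(features = features, labels = labels, loso = loso,
                 roc = roc, convergence = conv,
                 selection = sel, paths = paths))
}

loso_result_to_list <- function(result) {
  list(
    subjects = result$subjects,
    iterations = lapply(result$iterations, function(it) {
      it[c("subject_id", "label", "session_ids", "day_index",
           "session_probs", "mean_prob", "selected_features", "params",
           "fold_aucs", "importances")]
    }),
    config = list(classifier = result$config$classifier,
                  k_best = result$config$k_best,
                  n_folds = result$config$n_folds,
                  seed = result$config$seed))
}
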