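#' Classification pipeline configuration
#'
#' Settings for the leave-one-subject-out screening pipeline: the classifier
#' family, the select-k-best cap (ANOVA F-value scoring, default k = 5), the
#' nested cross-validation fold count (default 5), the hyperparameter grid,
#' and the fold/balancing policies.
#'
#' @param classifier One of `"random_forest"`, `"gradient_boosting"`,
#'   `"svm"`.
#' @param k_best Number of features the select-k-best step keeps (>= 1).
#' @param n_folds Nested cross-validation folds (>= 2).
#' @param grid Data frame of candidate hyperparameter combinations (one row
#'   per combination); `NULL` uses the classifier's default grid:
#'   random forest trees {100, 300} x depth {unlimited, 5, 10}; gradient
#'   boosting learning rate {0.05, 0.1} x stages {100, 300}; SVM cost
#'   {0.1, 1, 10} with an RBF kernel.
#' @param seed Integer seed controlling every random draw of the pipeline.
#' @param balance Under-sample the majority class to a balanced session-level
#'   training set in each iteration (default `TRUE`)?
#' @param subject_folds Group nested folds by subject so no subject straddles
#'   a fold boundary (default `TRUE`; `FALSE` gives session-level folds).
#' @param fold_rule `"best_fold"` takes the feature set and hyperparameters
#'   of the fold with the highest held-out AUC (the literal winner-fold
#'   rule); `"mean"` picks the hyperparameters with the best mean AUC across
#'   folds and selects features on the full training set.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(classifier = c("random_forest",
                                           "gradient_boosting", "svm"),
                            k_best = 5, n_folds = 5, grid = NULL, seed = 1,
                            balance = TRUE, subject_folds = TRUE,
                            fold_rule = c("best_fold", "mean")) {
  classifier <- match.arg(classifier)
  fold_rule <- match.arg(fold_rule)
  stopifnot(k_best >= 1, n_folds >= 2)
  if (is.null(grid)) grid <- default_grid(classifier)
  structure(list(classifier = classifier, k_best = as.integer(k_best),
                 n_folds = as.integer(n_folds), grid = grid,
                 seed = as.integer(seed), balance = isTRUE(balance),
                 subject_folds = isTRUE(subject_folds),
                 fold_rule = fold_rule),
            class = "pipeline_config")
}

#' Balance a session-level training set
#'
#' Randomly under-samples the majority class (seeded) so both classes
#' contribute the same number of session rows; the output row order is a
#' seeded shuffle.
#'
#' @param rows Feature rows with a `label` column (factor `HC`/`DT`).
#' @param seed Integer seed.
#' @return Balanced, shuffled rows.
#' @export
balance_training_sessions <- function(rows, seed) {
  counts <- table(rows$label)
  if (any(counts == 0)) {
    stop("degenerate training set: a class has zero sessions", call. = FALSE)
  }
  n_min <- min(counts)
  withr::with_seed(seed, {
    keep <- unlist(lapply(levels(rows$label), function(lv) {
      idx <- which(rows$label == lv)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
    rows[sample(keep), , drop = FALSE]
  })
}

#' ANOVA F-values of features against a grouping
#'
#' One-way analysis-of-variance F statistic per feature column, the scoring
#' function of the select-k-best step.
#'
#' @param X Numeric matrix (rows = sessions, columns = features).
#' @param y Group factor.
#' @return Named numeric vector of F statistics (0 for zero-variance
#'   features).
#' @export
anova_f_scores <- function(X, y) {
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  g <- nlevels(y)
  grand <- colMeans(X)
  ss_between <- 0
  ss_within <- 0
  for (lv in levels(y)) {
    Xg <- X[y == lv, , drop = FALSE]
    mg <- colMeans(Xg)
    ss_between <- ss_between + nrow(Xg) * (mg - grand)^2
    ss_within <- ss_within + colSums(sweep(Xg, 2, mg)^2)
  }
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  f[!is.finite(f)] <- 0
  f
}

select_k_best <- function(rows, feature_cols, k) {
  X <- as.matrix(rows[, feature_cols, drop = FALSE])
  f <- anova_f_scores(X, rows$label)
  feature_cols[order(-f)][seq_len(min(k, length(feature_cols)))]
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve via the rank formulation: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, ties
#' counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Factor/character labels; `positive` marks the positive
#'   class.
#' @param positive Positive class label (default `"DT"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels, positive = "DT") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

subject_mean_scores <- function(probs, subject_ids, labels) {
  agg <- tapply(probs, subject_ids, mean)
  lab <- tapply(as.character(labels), subject_ids, function(x) x[1])
  tibble::tibble(subject_id = names(agg),
                 prob = as.numeric(agg),
                 label = factor(as.character(lab), levels = c("HC", "DT")))
}

assign_subject_folds <- function(subjects, n_folds, seed) {
  withr::with_seed(seed, {
    perm <- sample(subjects)
    split(perm, rep_len(seq_len(n_folds), length(perm)))
  })
}

#' Nested feature selection and hyperparameter tuning
#'
#' The nested 5-fold stage of one LOSO iteration. The training rows are
#' segmented into folds (grouped by subject by default); in each fold pass,
#' the other folds select the k best features by ANOVA F-value and
#' grid-search the classifier hyperparameters, and the held-out fold scores
#' each candidate by the AUC of its subject-mean probabilities. Under the
#' winner-fold rule the (features, hyperparameters) pair of the fold with the
#' highest held-out AUC is returned (ties: lowest fold index).
#'
#' @param train_rows Balanced training rows: `subject_id`, `label` and the
#'   20 feature columns.
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed for fold assignment (defaults to `cfg$seed`).
#' @return List `features`, `params` (one-row data frame), `fold_aucs`,
#'   `winning_fold`.
#' @export
nested_select_and_tune <- function(train_rows, cfg, seed = cfg$seed) {
  feature_cols <- intersect(feature_names(), names(train_rows))
  subjects <- unique(train_rows$subject_id)
  if (cfg$subject_folds && length(subjects) < cfg$n_folds) {
    stop("need at least n_folds subjects in the training set", call. = FALSE)
  }
  folds <- NULL
  for (try in 0:10) {
    if (try == 10) {
      stop("could not build folds with both classes after 10 retries",
           call. = FALSE)
    }
    if (cfg$subject_folds) {
      fold_subjects <- assign_subject_folds(subjects, cfg$n_folds, seed + try)
      cand <- lapply(fold_subjects, function(ss)
        which(train_rows$subject_id %in% ss))
    } else {
      cand <- withr::with_seed(seed + try, {
        perm <- sample(nrow(train_rows))
        split(perm, rep_len(seq_len(cfg$n_folds), length(perm)))
      })
    }
    two_class <- vapply(cand, function(idx) {
      length(unique(train_rows$label[idx])) == 2 &&
        length(unique(train_rows$label[-idx])) == 2
    }, logical(1))
    if (all(two_class)) {
      folds <- cand
      break
    }
  }
  fold_results <- lapply(seq_along(folds), function(f) {
    hold_idx <- folds[[f]]
    inner <- train_rows[-hold_idx, , drop = FALSE]
    hold <- train_rows[hold_idx, , drop = FALSE]
    feats <- select_k_best(inner, feature_cols, cfg$k_best)
    std <- standardize_fit(inner, feats)
    Xin <- standardize_apply(inner, std)
    Xhold <- standardize_apply(hold, std)
    best <- list(auc = -Inf, params = NULL)
    for (gi in seq_len(nrow(cfg$grid))) {
      params <- as.list(cfg$grid[gi, , drop = FALSE])
      model <- fit_classifier(Xin, inner$label, cfg$classifier, params,
                              seed = seed + 101 * f + gi)
      probs <- predict_prob_dt(model, Xhold)
      sm <- subject_mean_scores(probs, hold$subject_id, hold$label)
      auc <- auc_rank(sm$prob, sm$label)
      if (!is.na(auc) && auc > best$auc) {
        best <- list(auc = auc, params = cfg$grid[gi, , drop = FALSE])
      }
    }
    list(features = feats, params = best$params, auc = best$auc)
  })
  aucs <- vapply(fold_results, function(fr) fr$auc, numeric(1))
  if (cfg$fold_rule == "best_fold") {
    win <- which.max(aucs) # which.max breaks ties by lowest index
    list(features = fold_results[[win]]$features,
         params = fold_results[[win]]$params,
         fold_aucs = aucs, winning_fold = win)
  } else {
    # mean rule: per-combination mean held-out AUC; features re-selected on
    # the full training set
    combo_aucs <- matrix(NA_real_, nrow(cfg$grid), length(folds))
    for (f in seq_along(folds)) {
      hold_idx <- folds[[f]]
      inner <- train_rows[-hold_idx, , drop = FALSE]
      hold <- train_rows[hold_idx, , drop = FALSE]
      feats <- select_k_best(inner, feature_cols, cfg$k_best)
      std <- standardize_fit(inner, feats)
      Xin <- standardize_apply(inner, std)
      Xhold <- standardize_apply(hold, std)
      for (gi in seq_len(nrow(cfg$grid))) {
        params <- as.list(cfg$grid[gi, , drop = FALSE])
        model <- fit_classifier(Xin, inner$label, cfg$classifier, params,
                                seed = seed + 101 * f + gi)
        probs <- predict_prob_dt(model, Xhold)
        sm <- subject_mean_scores(probs, hold$subject_id, hold$label)
        combo_aucs[gi, f] <- auc_rank(sm$prob, sm$label)
      }
    }
    gi <- which.max(rowMeans(combo_aucs, na.rm = TRUE))
    list(features = select_k_best(train_rows, feature_cols, cfg$k_best),
         params = cfg$grid[gi, , drop = FALSE],
         fold_aucs = aucs, winning_fold = NA_integer_)
  }
}

standardize_fit <- function(rows, features) {
  X <- as.matrix(rows[, features, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  drop <- scl == 0 | !is.finite(scl)
  if (any(drop)) {
    warning("dropping constant feature(s) after standardization: ",
            paste(features[drop], collapse = ", "), call. = FALSE)
  }
  list(features = features[!drop], center = ctr[!drop], scale = scl[!drop])
}

standardize_apply <- function(rows, std) {
  X <- as.matrix(rows[, std$features, drop = FALSE])
  scale(X, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Fit the final model of a LOSO iteration
#'
#' Trains the chosen classifier on all balanced training rows restricted to
#' the selected features, with feature standardization (zero mean, unit
#' variance, fit on training rows only) stored alongside.
#'
#' @param train_rows Balanced training rows.
#' @param features Selected feature names.
#' @param params One-row data frame of tuned hyperparameters.
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed.
#' @return A `keydyn_model` list with the fit, standardization and
#'   importances (tree-based classifiers).
#' @export
fit_final_model <- function(train_rows, features, params, cfg,
                            seed = cfg$seed) {
  std <- standardize_fit(train_rows, features)
  X <- standardize_apply(train_rows, std)
  model <- fit_classifier(X, train_rows$label, cfg$classifier,
                          as.list(params), seed = seed)
  structure(list(model = model, std = std, features = std$features,
                 params = params, classifier = cfg$classifier,
                 importances = model_importances(model)),
            class = "keydyn_model")
}

#' Predict a subject's depressive-tendency probability
#'
#' Scores each of the subject's typing sessions with the fitted model and
#' averages the session probabilities into the subject-level score.
#'
#' @param model A `keydyn_model` from [fit_final_model()].
#' @param subject_rows Feature rows of one subject (chronological order).
#' @param threshold Decision threshold on the mean probability (default
#'   0.5; a Youden threshold from [youden_operating_point()] may be used
#'   instead).
#' @return List `session_probs`, `mean_prob`, `decision` (`"DT"`/`"HC"`).
#' @export
predict_subject <- function(model, subject_rows, threshold = 0.5) {
  if (nrow(subject_rows) == 0) {
    stop("no valid sessions to predict for this subject", call. = FALSE)
  }
  X <- standardize_apply(subject_rows, model$std)
  probs <- predict_prob_dt(model$model, X)
  mean_prob <- mean(probs)
  list(session_probs = probs, mean_prob = mean_prob,
       decision = if (mean_prob >= threshold) "DT" else "HC")
}

#' Run the leave-one-subject-out screening pipeline
#'
#' One iteration per subject: the held-out subject's sessions are removed,
#' the remaining sessions are balanced by class (seeded under-sampling),
#' nested cross-validation selects features and hyperparameters, the final
#' model is fit, and the held-out subject's sessions are scored and averaged.
#'
#' @param features Feature table from [extract_features()].
#' @param labels Label table from [cohort_labels()].
#' @param cfg A [pipeline_config()].
#' @return A `loso_result` with per-subject probabilities and per-iteration
#'   selected features, hyperparameters, importances and training-row ids.
#' @export
run_loso <- function(features, labels, cfg = pipeline_config()) {
  rows <- dplyr::inner_join(features, labels[, c("subject_id", "label")],
                            by = "subject_id")
  rows$.row_id <- seq_len(nrow(rows))
  subjects <- unique(rows$subject_id)
  if (length(subjects) < 3) {
    stop("LOSO needs at least 3 subjects", call. = FALSE)
  }
  subj_labels <- labels$label[match(subjects, labels$subject_id)]
  if (length(unique(subj_labels)) < 2) {
    stop("single-class cohort: both DT and HC subjects are required",
         call. = FALSE)
  }
  iter_seeds <- withr::with_seed(cfg$seed,
    matrix(sample.int(.Machine$integer.max %/% 2, 3 * length(subjects)),
           ncol = 3))
  iterations <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test_rows <- rows[rows$subject_id == s, , drop = FALSE]
    train_rows <- rows[rows$subject_id != s, , drop = FALSE]
    if (cfg$balance) {
      train_rows <- balance_training_sessions(train_rows, iter_seeds[i, 1])
    }
    tuned <- nested_select_and_tune(train_rows, cfg, seed = iter_seeds[i, 2])
    model <- fit_final_model(train_rows, tuned$features, tuned$params, cfg,
                             seed = iter_seeds[i, 3])
    pred <- predict_subject(model, test_rows)
    iterations[[i]] <- list(
      subject_id = s,
      label = as.character(test_rows$label[1]),
      session_ids = test_rows$session_id,
      day_index = test_rows$day_index,
      session_probs = pred$session_probs,
      mean_prob = pred$mean_prob,
      selected_features = tuned$features,
      params = tuned$params,
      fold_aucs = tuned$fold_aucs,
      importances = model$importances,
      train_row_ids = train_rows$.row_id,
      test_row_ids = test_rows$.row_id)
  }
  subjects_tbl <- tibble::tibble(
    subject_id = subjects,
    label = factor(vapply(iterations, function(x) x$label, character(1)),
                   levels = c("HC", "DT")),
    mean_prob = vapply(iterations, function(x) x$mean_prob, numeric(1)),
    n_sessions = vapply(iterations, function(x) length(x$session_probs),
                        integer(1)))
  structure(list(subjects = subjects_tbl, iterations = iterations,
                 config = cfg),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  auc <- auc_rank(x$subjects$mean_prob, x$subjects$label)
  cat(sprintf("<loso_result> %d subjects (%d DT / %d HC), classifier %s\n",
              nrow(x$subjects), sum(x$subjects$label == "DT"),
              sum(x$subjects$label == "HC"), x$config$classifier))
  cat(sprintf("  subject-level AUC (point estimate): %.3f\n", auc))
  invisible(x)
}

#' Session probabilities of a LOSO result
#'
#' @param result A `loso_result`.
#' @return Tibble `subject_id`, `session_id`, `day_index`, `prob`, `label`.
#' @export
loso_session_probs <- function(result) {
  dplyr::bind_rows(lapply(result$iterations, function(it) {
    tibble::tibble(subject_id = it$subject_id, session_id = it$session_ids,
                   day_index = it$day_index, prob = it$session_probs,
                   label = it$label)
  }))
}

#' Feature selection-frequency report
#'
#' For each feature, the percentage of LOSO iterations in which the
#' select-k-best step kept it, and the mean (sd) impurity importance over
#' the iterations where it was selected. Features selected in at least 90%
#' of iterations are flagged as consistently selected.
#'
#' @param result A `loso_result`.
#' @param threshold_pct Consistency threshold (default 90).
#' @return Tibble `feature`, `times_selected`, `freq_pct`,
#'   `mean_importance`, `sd_importance`, `consistent`.
#' @export
selection_frequency_report <- function(result, threshold_pct = 90) {
  n_iter <- length(result$iterations)
  stopifnot(n_iter >= 1)
  feats <- feature_names()
  rows <- lapply(feats, function(f) {
    sel <- vapply(result$iterations,
                  function(it) f %in% it$selected_features, logical(1))
    imps <- unlist(lapply(result$iterations[sel], function(it) {
      if (is.null(it$importances)) NA_real_ else unname(it$importances[f])
    }))
    imps <- imps[!is.na(imps)]
    tibble::tibble(
      feature = f, times_selected = sum(sel),
      freq_pct = 100 * mean(sel),
      mean_importance = if (length(imps) > 0) mean(imps) else NA_real_,
      sd_importance = if (length(imps) > 1) sd(imps) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  out$consistent <- out$freq_pct >= threshold_pct
  dplyr::arrange(out, dplyr::desc(.data$freq_pct))
}
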