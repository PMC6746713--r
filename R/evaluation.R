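#' Youden operating point
#'
#' Sweeps all distinct score cutpoints (decision: positive iff score >=
#' threshold) and returns the one maximizing the Youden index
#' J = sensitivity + specificity - 1, the operating point under equal
#' misclassification cost. Ties are broken by higher sensitivity, then lower
#' threshold.
#'
#' @param scores Numeric subject scores.
#' @param labels Labels (`"DT"` positive by default).
#' @param positive Positive class label.
#' @return List `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_operating_point <- function(scores, labels, positive = "DT") {
  pos <- labels == positive
  if (sum(pos) == 0 || sum(!pos) == 0) {
    stop("both classes required for the Youden operating point", call. = FALSE)
  }
  thresholds <- sort(unique(scores))
  best <- NULL
  for (t in thresholds) {
    sens <- mean(scores[pos] >= t)
    spec <- mean(scores[!pos] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 && t < best$threshold)))) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   j = j)
    }
  }
  best
}

empirical_roc <- function(scores, labels, positive = "DT") {
  pos <- labels == positive
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  # collapse tied scores to the last point of each tie group
  keep <- rev(!duplicated(rev(scores[ord])))
  tibble::tibble(fpr = c(0, fp[keep] / sum(!pos)),
                 tpr = c(0, tp[keep] / sum(pos)))
}

tpr_at_grid <- function(roc, grid) {
  # right-continuous step interpolation (vertical averaging)
  approx(x = roc$fpr, y = roc$tpr, xout = grid, method = "constant",
         f = 0, ties = max, rule = 2)$y
}

#' Bootstrap ROC analysis
#'
#' Resamples subjects with replacement (the decision unit is the subject),
#' computes a rank-formulation AUC per replicate, and reports the mean AUC
#' with a percentile 95% confidence interval plus a vertically averaged mean
#' ROC curve on a fixed false-positive-rate grid. Replicates that draw a
#' single class are redrawn. The Youden operating point of the original
#' (un-resampled) scores is attached.
#'
#' @param scores Tibble with `prob` and `label` per subject (e.g.
#'   `loso_result$subjects` renamed, or any per-subject score table).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param fpr_grid False-positive-rate grid for curve averaging.
#' @return A `roc_summary` list: `auc_point`, `mean_auc`, `ci_low`,
#'   `ci_high`, `mean_curve` (tibble `fpr`, `tpr`), `threshold`,
#'   `sensitivity`, `specificity`, `n_bootstraps`, `boot_aucs`.
#' @export
bootstrap_roc <- function(scores, n_boot = 1000, seed = 1,
                          fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(n_boot >= 1)
  prob <- scores$prob
  label <- as.character(scores$label)
  if (sum(label == "DT") < 2 || sum(label == "HC") < 2) {
    stop("bootstrap ROC needs at least 2 subjects per class", call. = FALSE)
  }
  n <- length(prob)
  point_auc <- auc_rank(prob, label)
  boot_aucs <- numeric(n_boot)
  curve_mat <- matrix(NA_real_, n_boot, length(fpr_grid))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(label[idx])) == 2) break
      }
      boot_aucs[b] <- auc_rank(prob[idx], label[idx])
      curve_mat[b, ] <- tpr_at_grid(empirical_roc(prob[idx], label[idx]),
                                    fpr_grid)
    }
  })
  ci <- unname(quantile(boot_aucs, c(0.025, 0.975), type = 7))
  yj <- youden_operating_point(prob, label)
  structure(list(
    auc_point = point_auc, mean_auc = mean(boot_aucs),
    ci_low = ci[1], ci_high = ci[2],
    mean_curve = tibble::tibble(fpr = fpr_grid,
                                tpr = colMeans(curve_mat)),
    threshold = yj$threshold, sensitivity = yj$sensitivity,
    specificity = yj$specificity, n_bootstraps = n_boot,
    boot_aucs = boot_aucs),
    class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> mean AUC %.3f [%.3f-%.3f; 95%% CI over %d bootstraps]\n",
              x$mean_auc, x$ci_low, x$ci_high, x$n_bootstraps))
  cat(sprintf("  Youden threshold %.3f: sensitivity %.2f / specificity %.2f\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Group-wise Mann-Whitney feature tests
#'
#' Two-sided Mann-Whitney U test per feature, applied on the averaged values
#' of features per subject (sessions are averaged within subject first).
#' Raw p-values are reported by default; `adjust = "BH"` adds a
#' Benjamini-Hochberg column. The exact null distribution is used for small
#' groups (both groups <= `exact_max` and no ties), the normal approximation
#' with continuity/tie correction otherwise.
#'
#' @param features Feature table from [extract_features()].
#' @param labels Label table from [cohort_labels()].
#' @param adjust `"none"` (default, matching raw reporting) or `"BH"`.
#' @param exact_max Largest per-group size for the exact test (default 12).
#' @return Tibble `feature`, `u`, `p` (and `p_adj` when adjusted); skipped
#'   features (a group with < 2 subjects) carry `NA` with a flag.
#' @export
groupwise_feature_tests <- function(features, labels,
                                    adjust = c("none", "BH"),
                                    exact_max = 12) {
  adjust <- match.arg(adjust)
  feats <- intersect(feature_names(), names(features))
  subj_means <- features |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feats), mean),
                     .groups = "drop") |>
    dplyr::inner_join(labels[, c("subject_id", "label")], by = "subject_id")
  out <- dplyr::bind_rows(lapply(feats, function(f) {
    x <- subj_means[[f]][subj_means$label == "DT"]
    y <- subj_means[[f]][subj_means$label == "HC"]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(feature = f, u = NA_real_, p = NA_real_,
                            skipped = TRUE))
    }
    exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    tibble::tibble(feature = f, u = unname(wt$statistic), p = wt$p.value,
                   skipped = FALSE)
  }))
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Spearman correlation with PHQ-9 scores
#'
#' Spearman rank correlation (two-sided) between a per-subject quantity
#' (e.g. the prediction probability, or a feature's subject mean) and the
#' PHQ-9 compound scores.
#'
#' @param values Numeric per-subject values.
#' @param phq9_scores Paired PHQ-9 scores.
#' @return List `rho`, `p`, `n`; a constant input vector returns `NA` with
#'   a `degenerate` flag.
#' @export
correlation_with_phq9 <- function(values, phq9_scores) {
  stopifnot(length(values) == length(phq9_scores))
  if (length(unique(values)) < 2 || length(unique(phq9_scores)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = length(values),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(values, phq9_scores, method = "spearman",
                                  alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(values),
       degenerate = FALSE)
}

#' Covariate logistic regression test
#'
#' Maximum-likelihood logistic regression of the subject group (DT = 1) on
#' the prediction probability, age, education, gender, probability
#' convergence session count and average sessions per day, with intercept.
#' Reports the Wald z and two-sided p per coefficient. Perfect separation is
#' flagged (coefficients still reported, with a warning recorded).
#'
#' @param data One row per subject with columns `label` (factor `HC`/`DT`),
#'   `prediction`, `age`, `education`, `gender`, `convergence`,
#'   `sessions_per_day`; no missing values.
#' @return Tibble `term`, `estimate`, `std_error`, `z`, `p` (constant row
#'   first); attribute `converged` and `separation_warning`.
#' @export
covariate_logistic_test <- function(data) {
  req <- c("label", "prediction", "age", "education", "gender",
           "convergence", "sessions_per_day")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[, req])) stop("missing values in predictors", call. = FALSE)
  df <- data.frame(
    y = as.numeric(data$label == "DT"),
    age = as.numeric(data$age),
    education = if (is.numeric(data$education)) data$education
                else as.numeric(factor(data$education)) - 1,
    gender = if (is.numeric(data$gender)) data$gender
             else as.numeric(factor(data$gender)) - 1,
    convergence = as.numeric(data$convergence),
    sessions_per_day = as.numeric(data$sessions_per_day),
    prediction = as.numeric(data$prediction))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ age + education + gender + convergence + sessions_per_day +
          prediction, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = c("Constant", "Age", "Education", "Gender", "Convergence",
             "Sessions per day", "Prediction"),
    estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
    z = unname(cf[, 3]), p = unname(cf[, 4]))
  attr(out, "converged") <- fit$converged
  attr(out, "separation_warning") <- sep_warn
  out
}
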