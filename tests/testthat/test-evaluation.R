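# all-pairs concordance oracle: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, labels, positive = "DT") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# exhaustive threshold-sweep oracle for the Youden operating point
oracle_youden <- function(scores, labels, positive = "DT") {
  pos <- labels == positive
  best <- list(j = -Inf)
  for (t in sort(unique(scores))) {
    sens <- mean(scores[pos] >= t); spec <- mean(scores[!pos] < t)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sensitivity + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(sens - best$sensitivity) <= 1e-12 &&
         t < best$threshold)) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec, j = j)
    }
  }
  best
}

test_that("rank AUC equals the all-pairs concordance oracle and pROC", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 2) # rounded to force ties
    labels <- sample(c("DT", "HC"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels))
  }
  skip_if_not_installed("pROC")
  set.seed(52)
  for (i in 1:20) {
    scores <- runif(15); labels <- sample(c("DT", "HC"), 15, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(
      pROC::roc(labels, scores, levels = c("HC", "DT"), direction = "<"))))
    expect_equal(auc_rank(scores, labels), ref)
  }
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  set.seed(53)
  scores <- runif(20); labels <- rep(c("DT", "HC"), 10)
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(qlogis(scores), labels), a)
  expect_equal(auc_rank(exp(3 * scores), labels), a)
  expect_equal(auc_rank(rank(scores), labels), a)
})

test_that("Youden operating point matches the exhaustive sweep oracle", {
  set.seed(54)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    scores <- round(runif(n), sample(1:3, 1))
    labels <- sample(c("DT", "HC"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(youden_operating_point(scores, labels),
                 oracle_youden(scores, labels))
  }
  # perfect separation
  y <- youden_operating_point(c(0.9, 0.8, 0.2, 0.1), c("DT", "DT", "HC", "HC"))
  expect_equal(c(y$sensitivity, y$specificity, y$j), c(1, 1, 1))
  # all-identical scores are uninformative
  expect_equal(youden_operating_point(rep(0.5, 8), rep(c("DT", "HC"), 4))$j, 0)
})

test_that("bootstrap ROC reports sound summaries with subject resampling", {
  perfect <- tibble::tibble(prob = c(0.9, 0.85, 0.8, 0.2, 0.15, 0.1),
                            label = rep(c("DT", "HC"), each = 3))
  r <- bootstrap_roc(perfect, n_boot = 100, seed = 1)
  expect_equal(r$mean_auc, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(max(r$mean_curve$tpr), 1)
  # labels independent of scores: mean AUC near 0.5
  set.seed(55)
  null_scores <- tibble::tibble(prob = runif(60),
                                label = rep(c("DT", "HC"), 30))
  rn <- bootstrap_roc(null_scores, n_boot = 300, seed = 2)
  expect_gt(rn$mean_auc, 0.35)
  expect_lt(rn$mean_auc, 0.65)
  expect_true(rn$ci_low <= rn$mean_auc && rn$mean_auc <= rn$ci_high)
  expect_error(bootstrap_roc(perfect[c(1, 4, 5), ], n_boot = 10, seed = 1),
               "at least 2")
})

test_that("bootstrap CI width shrinks with subject count at fixed effect", {
  mk <- function(n) {
    withr::with_seed(56, tibble::tibble(
      prob = c(rnorm(n / 2, 0.65, 0.15), rnorm(n / 2, 0.45, 0.15)),
      label = rep(c("DT", "HC"), each = n / 2)))
  }
  small <- bootstrap_roc(mk(12), n_boot = 300, seed = 3)
  large <- bootstrap_roc(mk(60), n_boot = 300, seed = 3)
  expect_lt(large$ci_high - large$ci_low, small$ci_high - small$ci_low)
})

test_that("group-wise tests run on per-subject means with exact small-sample p-values", {
  # identical per-subject distributions in both groups -> p = 1
  subj <- sprintf("S%02d", 1:8)
  vals <- rep(c(1, 2, 3, 4), 2)
  features <- tibble::tibble(subject_id = rep(subj, each = 2),
                             session_id = paste0(rep(subj, each = 2), "-", 1:2),
                             day_index = 0L)
  for (f in feature_names()) features[[f]] <- rep(vals, each = 2)
  labels <- tibble::tibble(subject_id = subj,
                           label = factor(rep(c("DT", "HC"), each = 4),
                                          levels = c("HC", "DT")))
  res <- groupwise_feature_tests(features, labels)
  expect_true(all(res$p == 1))
  # complete separation of subject means -> minimal attainable exact p
  features2 <- features
  sep_vals <- c(10, 20, 30, 40, 1, 2, 3, 4)
  for (f in feature_names()) features2[[f]] <- rep(sep_vals, each = 2)
  res2 <- groupwise_feature_tests(features2, labels)
  expect_equal(unique(res2$p), 2 / choose(8, 4)) # exact two-sided minimum
  expect_equal(unique(res2$u), 16)               # n1 * n2, all pairs concordant
  # session-level imbalance must not leak: duplicating one subject's sessions
  # leaves the subject-mean test unchanged
  dup <- dplyr::bind_rows(features2, features2[features2$subject_id == "S01", ])
  expect_equal(groupwise_feature_tests(dup, labels)$p, res2$p)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(correlation_with_phq9(1:10, (1:10)^2)$rho, 1)
  expect_equal(correlation_with_phq9(1:10, 10:1)$rho, -1)
  set.seed(57)
  for (i in 1:40) {
    v <- rnorm(25); s <- sample(0:27, 25, replace = TRUE)
    r <- correlation_with_phq9(v, s)
    expect_equal(r$rho, cor(rank(v), rank(s)))
  }
  expect_true(correlation_with_phq9(rep(1, 10), 1:10)$degenerate)
})

test_that("the covariate logistic test reports seven coefficient rows", {
  set.seed(58)
  n <- 25
  df <- tibble::tibble(
    label = factor(sample(c("HC", "DT"), n, replace = TRUE, prob = c(0.55, 0.45)),
                   levels = c("HC", "DT")),
    prediction = runif(n), age = sample(18:39, n, replace = TRUE),
    education = sample(c("high-school", "university"), n, replace = TRUE),
    gender = sample(c("F", "M"), n, replace = TRUE),
    convergence = sample(10:120, n, replace = TRUE),
    sessions_per_day = runif(n, 10, 90))
  tab <- covariate_logistic_test(df)
  expect_equal(nrow(tab), 7)
  expect_identical(tab$term[1], "Constant")
  expect_identical(tab$term[7], "Prediction")
  expect_true(all(is.finite(tab$p)))
  df$prediction[1] <- NA
  expect_error(covariate_logistic_test(df), "missing values")
})

test_that("the logistic test recovers a planted log-odds and is calibrated under the null", {
  set.seed(59)
  n <- 600
  pred <- rbinom(n, 1, 0.5)
  eta <- -0.5 + 1.5 * pred
  y <- rbinom(n, 1, plogis(eta))
  df <- tibble::tibble(
    label = factor(ifelse(y == 1, "DT", "HC"), levels = c("HC", "DT")),
    prediction = pred, age = rnorm(n, 24, 4),
    education = rbinom(n, 1, 0.3), gender = rbinom(n, 1, 0.5),
    convergence = rnorm(n, 50, 10), sessions_per_day = rnorm(n, 60, 20))
  tab <- covariate_logistic_test(df)
  est <- tab$estimate[tab$term == "Prediction"]
  expect_lt(abs(est - 1.5), 0.45)
  # outcome independent of predictors: slope p-values not systematically small
  y0 <- rbinom(n, 1, 0.5)
  df$label <- factor(ifelse(y0 == 1, "DT", "HC"), levels = c("HC", "DT"))
  tab0 <- covariate_logistic_test(df)
  expect_gt(mean(tab0$p[-1]), 0.05)
})
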