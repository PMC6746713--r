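# Internal classifier dispatch. All models receive a standardized numeric
# matrix and a factor y with levels c("HC", "DT"); they return calibrated
# probabilities of the positive (DT) class.

default_grid <- function(classifier) {
  switch(classifier,
    random_forest = expand.grid(num_trees = c(100, 300),
                                max_depth = c(0, 5, 10)),
    gradient_boosting = expand.grid(eta = c(0.05, 0.1),
                                    nrounds = c(100, 300)),
    svm = data.frame(cost = c(0.1, 1, 10)),
    stop("unknown classifier: ", classifier, call. = FALSE))
}

fit_classifier <- function(X, y, classifier, params, seed) {
  if (classifier == "random_forest") {
    md <- params$max_depth
    fit <- ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = params$num_trees,
      max.depth = if (is.null(md) || md == 0) NULL else md,
      importance = "impurity",
      seed = seed, num.threads = 1)
    list(classifier = classifier, fit = fit, features = colnames(X))
  } else if (classifier == "gradient_boosting") {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "DT"))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = 3, nthread = 1, seed = seed),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
    list(classifier = classifier, fit = fit, features = colnames(X))
  } else if (classifier == "svm") {
    fit <- withr::with_seed(seed, e1071::svm(
      x = X, y = y, kernel = "radial", cost = params$cost,
      probability = TRUE, scale = FALSE))
    list(classifier = classifier, fit = fit, features = colnames(X))
  } else {
    stop("unknown classifier: ", classifier, call. = FALSE)
  }
}

predict_prob_dt <- function(model, X) {
  X <- X[, model$features, drop = FALSE]
  if (model$classifier == "random_forest") {
    p <- predict(model$fit, data = X, num.threads = 1)$predictions
    as.numeric(p[, "DT"])
  } else if (model$classifier == "gradient_boosting") {
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X)))
  } else {
    pr <- predict(model$fit, newdata = X, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "DT"])
  }
}

model_importances <- function(model) {
  if (model$classifier == "random_forest") {
    imp <- ranger::importance(model$fit)
    # normalise impurity importances to sum to 1, matching the convention of
    # reporting relative GINI importance shares
    if (sum(imp) > 0) imp <- imp / sum(imp)
    imp[model$features]
  } else if (model$classifier == "gradient_boosting") {
    tab <- xgboost::xgb.importance(model = model$fit)
    imp <- setNames(rep(0, length(model$features)), model$features)
    if (!is.null(tab) && nrow(tab) > 0) imp[tab$Feature] <- tab$Gain
    imp
  } else {
    NULL
  }
}
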