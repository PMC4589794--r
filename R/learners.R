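# Learner wrappers sharing a fit(x, y) / predict(model, x) contract so the
# element-model machinery can swap the regression engine (random forest by
# default; multivariate linear regression and support vector regression as
# alternatives for robustness comparisons).

fit_learner <- function(x, y, learner = "rf", ntree = 500,
                        sample_frac = 0.7, mtry_frac = 0.3) {
  const <- stats::var(y) == 0
  if (const) warning("degenerate constant target for learner fit")
  n <- nrow(x); p <- ncol(x)
  rf_fit <- function() randomForest::randomForest(
    x = x, y = y, ntree = ntree,
    mtry = max(1, floor(mtry_frac * p)),
    sampsize = max(2, ceiling(sample_frac * n)), replace = TRUE)
  mod <- switch(learner,
    rf = if (const) suppressWarnings(rf_fit()) else rf_fit(),
    mlr = {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::lm(y ~ ., data = df))
    },
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("the svr learner requires the e1071 package")
      e1071::svm(x = x, y = y)
    },
    stop("unknown learner: ", learner))
  structure(list(learner = learner, model = mod), class = "mesic_learner")
}

predict_learner <- function(fit, x) {
  p <- switch(fit$learner,
    rf = stats::predict(fit$model, x),
    mlr = {
      cf <- stats::coef(fit$model)
      cf[is.na(cf)] <- 0
      as.numeric(cbind(1, x[, names(cf)[-1], drop = FALSE]) %*% cf)
    },
    svr = as.numeric(stats::predict(fit$model, x)))
  clamp01(as.numeric(p))
}
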