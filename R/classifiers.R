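# Classifier wrappers with the study's fixed hyperparameters. The solvers are
# delegated (rpart, e1071::svm, ranger); AdaBoost (discrete SAMME with
# depth-1 rpart stumps) is implemented here. Every wrapper exposes the same
# fit/predict surface returning a hard class and a continuous case-tendency
# score, so the harness treats them uniformly. The positive class is "case"
# (patients).

#' Classifier specification
#'
#' Hyperparameter defaults follow the study protocol. Decision tree: binary
#' splits, minimum split subset 5, maximum depth 20. SVM: RBF kernel, cost 1,
#' numerical tolerance 0.10 (features z-scored per training fold). Random
#' forest: phase-specific settings — T-wave: 29 trees, 5 attributes per
#' split, depth 8; R-wave: 28 trees, 3 attributes per split, depth 5.
#' AdaBoost: tree base estimator (depth-1 stumps), 50 estimators, learning
#' rate 0.1.
#'
#' @param kind one of `"decision_tree"`, `"svm_rbf"`, `"random_forest"`,
#'   `"adaboost"`.
#' @param phase `"R"` or `"T"`; selects the random-forest parameter set.
#' @param ... overrides for individual hyperparameters.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("decision_tree", "svm_rbf",
                                     "random_forest", "adaboost"),
                            phase = c("R", "T"), ...) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  defaults <- switch(kind,
    decision_tree = list(minsplit = 5, maxdepth = 20),
    svm_rbf = list(cost = 1, tolerance = 0.10),
    random_forest = if (phase == "T") {
      list(num_trees = 29, mtry = 5, max_depth = 8)
    } else {
      list(num_trees = 28, mtry = 3, max_depth = 5)
    },
    adaboost = list(n_estimators = 50, learning_rate = 0.1, base_depth = 1)
  )
  structure(c(list(kind = kind, phase = phase),
              utils::modifyList(defaults, list(...))),
            class = "classifier_spec")
}

#' Default classifier battery for one phase
#'
#' @param phase `"R"` or `"T"`.
#' @return named list of four [classifier_spec()] objects.
#' @export
default_classifier_specs <- function(phase = c("R", "T")) {
  phase <- match.arg(phase)
  kinds <- c("decision_tree", "svm_rbf", "random_forest", "adaboost")
  stats::setNames(lapply(kinds, classifier_spec, phase = phase), kinds)
}

#' Fit a classifier on a training matrix
#'
#' @param spec a [classifier_spec()].
#' @param x numeric matrix, samples x features.
#' @param y binary labels (1 = case).
#' @param seed seed for stochastic learners (random forest).
#' @return fitted model object for [predict_classifier()].
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as_binary_labels(y)
  x <- as.matrix(x)
  if (length(unique(y)) < 2) {
    return(structure(list(kind = "majority", vote = as.integer(
      round(mean(y)))), class = "echotexture_model"))
  }
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  df$.y <- factor(y, levels = c(0, 1))
  fit <- switch(spec$kind,
    decision_tree = rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(minsplit = spec$minsplit,
                                     maxdepth = spec$maxdepth,
                                     cp = 0, xval = 0)),
    svm_rbf = {
      mu <- colMeans(x)
      sd_ <- apply(x, 2, stats::sd)
      sd_[sd_ == 0] <- 1
      xs <- scale(x, center = mu, scale = sd_)
      m <- e1071::svm(xs, df$.y, type = "C-classification",
                      kernel = "radial", cost = spec$cost,
                      tolerance = spec$tolerance, scale = FALSE)
      list(svm = m, mu = mu, sd = sd_)
    },
    random_forest = ranger::ranger(
      .y ~ ., data = df, num.trees = spec$num_trees,
      mtry = min(spec$mtry, ncol(x)), max.depth = spec$max_depth,
      probability = TRUE, seed = seed, num.threads = 1),
    adaboost = adaboost_fit(x, y, n_estimators = spec$n_estimators,
                            learning_rate = spec$learning_rate,
                            base_depth = spec$base_depth)
  )
  structure(list(kind = spec$kind, fit = fit,
                 feature_names = names(df)[names(df) != ".y"]),
            class = "echotexture_model")
}

#' Predict class labels and case-tendency scores
#'
#' @param model fitted model from [fit_classifier()].
#' @param x numeric matrix of test samples.
#' @return list with `class` (0/1 vector) and `score` (continuous case
#'   tendency; larger = more case-like).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "echotexture_model"))
  x <- as.matrix(x)
  if (model$kind == "majority") {
    n <- nrow(x)
    return(list(class = rep(model$vote, n), score = rep(model$vote, n)))
  }
  df <- as.data.frame(x)
  names(df) <- model$feature_names
  switch(model$kind,
    decision_tree = {
      p <- predict(model$fit, df)[, "1"]
      list(class = as.integer(p >= 0.5), score = p)
    },
    svm_rbf = {
      xs <- scale(x, center = model$fit$mu, scale = model$fit$sd)
      pred <- predict(model$fit$svm, xs, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # orient the decision value so larger = case
      if (grepl("^0", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
      list(class = as.integer(as.character(pred)), score = dv)
    },
    random_forest = {
      p <- predict(model$fit, df, num.threads = 1)$predictions[, "1"]
      list(class = as.integer(p >= 0.5), score = p)
    },
    adaboost = adaboost_predict(model$fit, x)
  )
}

# Discrete AdaBoost (SAMME) with shrinkage; base learner: rpart stump of
# depth `base_depth`. Stops early on a perfect or uninformative stump.
adaboost_fit <- function(x, y, n_estimators = 50, learning_rate = 0.1,
                         base_depth = 1) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(df), unique = TRUE)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = base_depth, minsplit = 2, cp = 0,
                          xval = 0))
    pred <- as.integer(predict(fit, df, type = "class") == "1")
    err <- sum(w * (pred != y))
    if (err <= 1e-12) {  # perfect stump: keep it with a large finite weight
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, learning_rate * log(1e12))
      break
    }
    if (err >= 0.5) break  # no better than chance: stop boosting
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {
    return(list(majority = as.integer(round(mean(y)))))
  }
  list(stumps = stumps, alphas = alphas,
       feature_names = names(df)[names(df) != ".y"])
}

adaboost_predict <- function(fit, x) {
  n <- nrow(x)
  if (!is.null(fit$majority)) {
    return(list(class = rep(fit$majority, n), score = rep(fit$majority, n)))
  }
  df <- as.data.frame(x)
  names(df) <- fit$feature_names
  margin <- numeric(n)
  for (m in seq_along(fit$stumps)) {
    pm <- as.integer(predict(fit$stumps[[m]], df, type = "class") == "1")
    margin <- margin + fit$alphas[m] * (2 * pm - 1)
  }
  score <- margin / sum(abs(fit$alphas))
  list(class = as.integer(margin > 0), score = score)
}
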