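# Pluggable binary-classifier interface and the default model suite:
# ridge logistic regression (glmnet), k-nearest neighbors (FNN), a primal
# squared-hinge linear SVM, and three tree ensembles (random forest,
# extremely randomized trees, gradient boosting) on the package's CART
# backend. Every model exposes fit / predict_score (class-1 probability in
# [0,1]) and, where available, an intrinsic importance.

#' Define a classifier for the pathway ML harness
#'
#' @param name model label.
#' @param fit `function(x, y)` -> fitted object (`x` numeric matrix, `y` 0/1).
#' @param predict_score `function(model, x)` -> class-1 score in \[0,1\].
#' @param importance optional `function(model)` -> non-negative named vector
#'   of intrinsic importances (NULL = use the permutation fallback).
#' @return list of class `ml_model`.
#' @export
ml_model <- function(name, fit, predict_score, importance = NULL) {
  structure(list(name = name, fit = fit, predict_score = predict_score,
                 importance = importance), class = "ml_model")
}

model_logistic <- function(lambda = 0.01) {
  ml_model(
    "logistic",
    fit = function(x, y) {
      if (ncol(x) >= 2) {
        glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                       standardize = FALSE)
      } else {
        structure(glm.fit(cbind(1, x), y, family = binomial()),
                  class = "nl_glm1")
      }
    },
    predict_score = function(m, x) {
      if (inherits(m, "nl_glm1"))
        as.numeric(1 / (1 + exp(-(cbind(1, x) %*% m$coefficients))))
      else
        as.numeric(predict(m, newx = x, type = "response"))
    },
    importance = function(m) {
      co <- if (inherits(m, "nl_glm1")) m$coefficients[-1] else
        as.numeric(coef(m))[-1]
      abs(co)
    })
}

model_knn <- function(k = 5) {
  ml_model(
    "knn",
    fit = function(x, y) list(x = x, y = y, k = min(k, nrow(x))),
    predict_score = function(m, x) {
      nn <- FNN::get.knnx(m$x, x, k = m$k)$nn.index
      rowMeans(matrix(m$y[nn], nrow(x), m$k))
    })
}

# primal L2-regularized squared-hinge linear SVM, full-batch gradient
# descent with a fixed step schedule (deterministic, no tuning)
model_svm <- function(lambda = 0.01, iters = 300) {
  ml_model(
    "svm_linear",
    fit = function(x, y) {
      y2 <- ifelse(y > 0, 1, -1)
      n <- nrow(x); p <- ncol(x)
      w <- numeric(p); b <- 0
      lr <- 1 / (max(colSums(x^2)) / n + lambda)
      for (it in seq_len(iters)) {
        m <- as.numeric(x %*% w + b) * y2
        act <- pmax(0, 1 - m)
        gw <- -(2 / n) * as.numeric(crossprod(x, y2 * act)) + 2 * lambda * w
        gb <- -(2 / n) * sum(y2 * act)
        w <- w - lr * gw
        b <- b - lr * gb
      }
      list(w = w, b = b)
    },
    predict_score = function(m, x)
      as.numeric(1 / (1 + exp(-(x %*% m$w + m$b)))),
    importance = function(m) abs(m$w))
}

model_random_forest <- function(ntree = 100, max_depth = 6, min_node = 2) {
  ml_model(
    "random_forest",
    fit = function(x, y) {
      mtry <- max(1L, floor(sqrt(ncol(x))))
      .fit_forest_cpp(x, as.numeric(y), ntree, mtry, max_depth, min_node,
                      bootstrap = TRUE, random_split = FALSE)
    },
    predict_score = function(m, x) .predict_forest_cpp(m$trees, x),
    importance = function(m) m$importance)
}

model_extra_trees <- function(ntree = 100, max_depth = 6, min_node = 2) {
  ml_model(
    "extra_trees",
    fit = function(x, y) {
      mtry <- max(1L, floor(sqrt(ncol(x))))
      .fit_forest_cpp(x, as.numeric(y), ntree, mtry, max_depth, min_node,
                      bootstrap = FALSE, random_split = TRUE)
    },
    predict_score = function(m, x) .predict_forest_cpp(m$trees, x),
    importance = function(m) m$importance)
}

model_gradient_boosting <- function(nrounds = 100, max_depth = 2,
                                    learning_rate = 0.1, min_node = 2,
                                    subsample = 1) {
  ml_model(
    "gradient_boosting",
    fit = function(x, y)
      .fit_gbm_cpp(x, as.numeric(y), nrounds, max_depth, learning_rate,
                   min_node, subsample),
    predict_score = function(m, x) .predict_gbm_cpp(m, x),
    importance = function(m) m$importance)
}

#' The default classifier suite
#'
#' Six classical models spanning linear, instance-based, margin-based and
#' ensemble tiers: regularized logistic regression, k-nearest neighbors, a
#' linear support-vector classifier, random forest, extremely randomized
#' trees and gradient boosting. Deep tabular adapters can be added through
#' [ml_model()] but are not part of the default suite.
#'
#' @param ntree trees per forest-style ensemble / boosting rounds.
#' @return named list of `ml_model` objects.
#' @export
default_model_suite <- function(ntree = 100) {
  suite <- list(model_logistic(), model_knn(), model_svm(),
                model_random_forest(ntree = ntree),
                model_extra_trees(ntree = ntree),
                model_gradient_boosting(nrounds = ntree))
  names(suite) <- vapply(suite, `[[`, character(1), "name")
  suite
}
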