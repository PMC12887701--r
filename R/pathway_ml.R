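# Pathway-restricted supervised evaluation: leakage-safe preprocessing,
# stratified cross-validation over the pluggable model suite, six-metric
# scoring, composite ranking, and importance extraction.

#' Fit the preprocessing pipeline on training data
#'
#' Three sequential steps, all fitted on (and only on) the rows supplied:
#' (1) per-gene Z-scoring with the sample SD, (2) removal of near-constant
#' genes (`variance < var_eps` before scaling), (3) univariate ANOVA F-test
#' selection at `P < f_alpha`. If fewer than 2 genes survive selection, the
#' 10 smallest-p genes are kept instead (logged), so downstream models always
#' see a usable feature set.
#'
#' @param x samples x genes numeric matrix.
#' @param y binary labels (0/1 or a two-level factor).
#' @param var_eps variance floor (default 1e-8).
#' @param f_alpha F-test retention threshold (default 0.01).
#' @return object of class `nl_preprocess` (apply with [apply_preprocess()]),
#'   or a status object of class `nl_empty_features` when nothing survives
#'   even the fallback.
#' @export
fit_preprocess <- function(x, y, var_eps = 1e-8, f_alpha = 0.01) {
  y <- as_binary_labels(y)
  stopifnot(nrow(x) == length(y), min(table(y)) >= 2)
  v <- matrixStats::colVars(x)
  keep_var <- which(v >= var_eps)
  if (!length(keep_var))
    return(structure(list(), class = "nl_empty_features"))
  xs <- x[, keep_var, drop = FALSE]
  mu <- colMeans(xs)
  sdv <- sqrt(matrixStats::colVars(xs))
  z <- sweep(sweep(xs, 2, mu), 2, sdv, "/")
  pvals <- anova_f_pvals(z, y)
  sel <- which(pvals < f_alpha)
  if (length(sel) < 2) {
    message("fewer than 2 genes at F-test P < ", f_alpha,
            "; falling back to the 10 smallest-p genes")
    sel <- order(pvals)[seq_len(min(10L, length(pvals)))]
  }
  structure(list(genes = colnames(x)[keep_var][sel],
                 mean = mu[sel], sd = sdv[sel],
                 f_pvals = pvals[sel]),
            class = "nl_preprocess")
}

#' @rdname fit_preprocess
#' @param pp a fitted `nl_preprocess`.
#' @param newx samples x genes matrix to transform (must contain the fitted
#'   genes).
#' @export
apply_preprocess <- function(pp, newx) {
  stopifnot(inherits(pp, "nl_preprocess"),
            all(pp$genes %in% colnames(newx)))
  z <- sweep(sweep(newx[, pp$genes, drop = FALSE], 2, pp$mean), 2, pp$sd, "/")
  z
}

# two-group ANOVA F-test p-value per column (F = t^2 on 1 and n-2 df)
anova_f_pvals <- function(x, y) {
  y <- as_binary_labels(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  m0 <- colMeans(x[y == 0, , drop = FALSE])
  ss1 <- matrixStats::colVars(x[y == 1, , drop = FALSE]) * (n1 - 1)
  ss0 <- matrixStats::colVars(x[y == 0, , drop = FALSE]) * (n0 - 1)
  s2 <- (ss1 + ss0) / (n - 2)
  f <- (m1 - m0)^2 / (s2 * (1 / n1 + 1 / n0))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(f)] <- 1
  p
}

as_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("labels must have exactly two levels")
    as.integer(as.character(y) == lev[1])  # first level alphabetically = 1
  } else {
    stopifnot(all(y %in% c(0, 1)))
    as.integer(y)
  }
}

#' Six classification metrics from scores and labels
#'
#' AUC is the rank-based (Mann-Whitney) estimate; accuracy, F1, precision,
#' recall and Cohen's kappa threshold the score at 0.5. Undefined ratios
#' (empty denominators) evaluate to 0.
#'
#' @param scores class-1 scores in \[0,1\].
#' @param labels 0/1 labels.
#' @return named numeric vector `auc accuracy f1 precision recall kappa`.
#' @export
classification_metrics <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  c(auc = auc, accuracy = acc, f1 = f1, precision = prec, recall = rec,
    kappa = kappa)
}

# stratified fold assignment: within each class, shuffled then dealt
# cyclically across folds
stratified_folds <- function(y, k, seed) {
  y <- as_binary_labels(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified cross-validated evaluation of a model suite
#'
#' Preprocessing (Z-score, variance filter, F-test selection) is fitted
#' inside each training fold only, so no information leaks from held-out
#' samples. Metrics are computed per fold and averaged. When a class has
#' fewer members than `k`, the fold count is lowered to the minimum class
#' count (logged). A `global_preprocess = TRUE` switch instead fits the
#' preprocessing once on the full data before splitting, reproducing a
#' pre-modeling pipeline at the cost of leakage.
#'
#' @param x samples x genes matrix.
#' @param y binary labels.
#' @param suite named list of [ml_model()] objects
#'   (default [default_model_suite()]).
#' @param k number of folds (default 10).
#' @param seed integer seed fixing fold assignment and any model randomness.
#' @param var_eps,f_alpha preprocessing parameters.
#' @param global_preprocess fit preprocessing globally instead of per fold.
#' @return data.frame of class `model_metrics`: one row per model with the
#'   six fold-averaged metrics.
#' @export
crossval_evaluate <- function(x, y, suite = default_model_suite(), k = 10,
                              seed = 1L, var_eps = 1e-8, f_alpha = 0.01,
                              global_preprocess = FALSE) {
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  min_class <- min(table(y))
  if (min_class < k) {
    message("lowering fold count from ", k, " to ", min_class,
            " (smallest class count)")
    k <- min_class
  }
  fold <- stratified_folds(y, k, seed)
  global_pp <- if (global_preprocess)
    fit_preprocess(x, y, var_eps, f_alpha) else NULL
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    pp <- if (global_preprocess) global_pp else
      fit_preprocess(x[tr, , drop = FALSE], y[tr], var_eps, f_alpha)
    if (inherits(pp, "nl_empty_features")) next
    xtr <- apply_preprocess(pp, x[tr, , drop = FALSE])
    xte <- apply_preprocess(pp, x[te, , drop = FALSE])
    per_fold[[f]] <- vapply(suite, function(mod) {
      fitted <- withr::with_seed(child_seed(seed, f), mod$fit(xtr, y[tr]))
      classification_metrics(mod$predict_score(fitted, xte), y[te])
    }, numeric(6))
  }
  per_fold <- per_fold[!vapply(per_fold, is.null, logical(1))]
  if (!length(per_fold)) stop("empty feature set in every fold")
  avg <- Reduce(`+`, per_fold) / length(per_fold)
  out <- data.frame(model = colnames(avg), t(avg), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("model_metrics", "data.frame")
  out
}

#' Composite rank across the six metrics
#'
#' Per metric, models are ranked 1 = best with averaged ties; the composite
#' is the sum of the six ranks (lower is better). Invariant to metric and
#' model ordering.
#'
#' @param metrics a `model_metrics` data.frame from [crossval_evaluate()].
#' @param top_n how many top models to flag (default 5).
#' @return data.frame `model`, `composite`, `top` sorted by ascending
#'   composite (ties by model name).
#' @export
composite_rank <- function(metrics, top_n = 5) {
  stopifnot(nrow(metrics) >= 2)
  cols <- c("auc", "accuracy", "f1", "precision", "recall", "kappa")
  stopifnot(all(cols %in% names(metrics)))
  ranks <- vapply(cols, function(cl) rank_desc(metrics[[cl]]),
                  numeric(nrow(metrics)))
  out <- data.frame(model = metrics$model, composite = rowSums(ranks),
                    stringsAsFactors = FALSE)
  out <- out[order(out$composite, out$model), ]
  out$top <- seq_len(nrow(out)) <= top_n
  rownames(out) <- NULL
  out
}

#' Extract a normalized per-gene importance vector from a fitted model
#'
#' Uses the model's intrinsic importance (coefficient magnitude or split
#' gain) where available; otherwise falls back to permutation importance
#' (mean AUC drop over `n_perm` column shuffles). The returned vector is
#' clipped at zero and normalized to sum 1; the `method` attribute records
#' which route was taken.
#'
#' @param model an [ml_model()].
#' @param fitted the fitted object from `model$fit`.
#' @param x,y the (preprocessed) feature matrix and labels used for the
#'   permutation fallback.
#' @param n_perm permutation repeats (default 20).
#' @param seed integer seed for the permutation fallback.
#' @return named numeric vector over `colnames(x)` summing to 1, with
#'   attribute `"method"` in `c("intrinsic", "permutation")`.
#' @export
extract_importance <- function(model, fitted, x, y, n_perm = 20, seed = 1L) {
  y <- as_binary_labels(y)
  if (!is.null(model$importance)) {
    imp <- model$importance(fitted)
    method <- "intrinsic"
  } else {
    base <- classification_metrics(model$predict_score(fitted, x), y)[["auc"]]
    imp <- withr::with_seed(seed, vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_perm), function(r) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        base - classification_metrics(model$predict_score(fitted, xp),
                                      y)[["auc"]]
      }, numeric(1))
      mean(drops)
    }, numeric(1)))
    method <- "permutation"
  }
  imp <- normalize_importance(imp)
  names(imp) <- colnames(x)
  attr(imp, "method") <- method
  imp
}

#' Aggregate top-model importances with inverse-position weights
#'
#' The model in top-5 position r carries weight 1/r; a gene absent from a
#' model's feature set contributes importance 0 there. The aggregate is the
#' weighted mean across models.
#'
#' @param importance_vectors list (in top-rank order, best first) of
#'   normalized importance vectors.
#' @return named numeric vector over the union of genes.
#' @export
weighted_importance <- function(importance_vectors) {
  stopifnot(length(importance_vectors) >= 1)
  genes <- unique(unlist(lapply(importance_vectors, names)))
  w <- 1 / seq_along(importance_vectors)
  acc <- setNames(numeric(length(genes)), genes)
  for (i in seq_along(importance_vectors)) {
    v <- importance_vectors[[i]]
    acc[names(v)] <- acc[names(v)] + w[i] * v
  }
  acc / sum(w)
}

#' Evaluate one pathway-restricted feature space end to end
#'
#' Cross-validates the suite, computes composite ranks, refits the top
#' models on the full (preprocessed) data and extracts their importances.
#'
#' @inheritParams crossval_evaluate
#' @param top_n models whose importances are extracted (default 5).
#' @param n_perm permutation repeats for models without intrinsic
#'   importance (default 10; lower values trade precision for speed).
#' @return list with `metrics`, `ranks`, and `importances` (one named,
#'   normalized vector per top model, best first).
#' @export
evaluate_pathway <- function(x, y, suite = default_model_suite(), k = 10,
                             seed = 1L, top_n = 5, f_alpha = 0.01,
                             n_perm = 10) {
  y <- as_binary_labels(y)
  metrics <- crossval_evaluate(x, y, suite, k = k, seed = seed,
                               f_alpha = f_alpha)
  ranks <- composite_rank(metrics, top_n = top_n)
  pp <- fit_preprocess(x, y, f_alpha = f_alpha)
  xall <- apply_preprocess(pp, x)
  top_models <- ranks$model[ranks$top]
  importances <- lapply(top_models, function(nm) {
    mod <- suite[[nm]]
    fitted <- withr::with_seed(child_seed(seed, 1000L), mod$fit(xall, y))
    extract_importance(mod, fitted, xall, y, n_perm = n_perm,
                       seed = child_seed(seed, 2000L))
  })
  names(importances) <- top_models
  list(metrics = metrics, ranks = ranks, importances = importances)
}
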