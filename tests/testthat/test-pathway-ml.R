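# Preprocessing, CV harness, metrics, composite ranks, importances.

toy_matrix <- function(n = 40, p = 12, seed = 1, shift_cols = 1:3,
                       shift = 2) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("g", seq_len(p))))
    y <- rep(c(1L, 0L), each = n / 2)
    x[y == 1, shift_cols] <- x[y == 1, shift_cols] + shift
    list(x = x, y = y)
  })
}

test_that("preprocess: Z-scoring, variance filter, F-test selection", {
  x <- cbind(g1 = c(1, 2, 3, 4), g2 = rep(5, 4), g3 = c(0, 10, 0.1, 10.2))
  y <- c(1, 0, 1, 0)
  # z-scoring uses the training mean and sample SD (n - 1 denominator):
  # applying the fit to (1, 2, 3) with mean 2 and sample SD 1 gives (-1, 0, 1)
  xtr <- cbind(a = c(1, 2, 3, 1, 2, 3), b = c(5, 1, 3, 2, 4, 6))
  pp1 <- fit_preprocess(xtr, c(1, 1, 1, 0, 0, 0), f_alpha = 1)
  expect_equal(unname(pp1$mean["a"]), 2)
  expect_equal(unname(pp1$sd["a"]), sd(c(1, 2, 3, 1, 2, 3)))
  z <- apply_preprocess(pp1, cbind(a = c(1, 2, 3) * pp1$sd["a"] + 2,
                                   b = c(1, 2, 3)))
  expect_equal(unname(z[, "a"]), c(1, 2, 3))
  # constant gene is removed by the variance filter
  pp2 <- fit_preprocess(x, y, f_alpha = 1)
  expect_false("g2" %in% pp2$genes)
  # F = t^2 fixture: groups (1,2,3) vs (4,5,6) give F = 13.5, P ~ 0.021,
  # dropped at alpha = 0.01 while a stronger gene stays
  xf <- cbind(weak = c(1, 2, 3, 4, 5, 6),
              strong = c(0, 0.1, -0.1, 8, 8.1, 7.9),
              strong2 = c(0, 0.2, -0.2, 9, 9.1, 8.9))
  yf <- c(1, 1, 1, 0, 0, 0)
  pv <- pf(13.5, 1, 4, lower.tail = FALSE)
  expect_equal(pv, 0.0213, tolerance = 1e-3)
  pp3 <- fit_preprocess(xf, yf, f_alpha = 0.01)
  expect_false("weak" %in% pp3$genes)
  expect_true(all(c("strong", "strong2") %in% pp3$genes))
  # fallback: nothing significant -> 10 smallest-p genes kept, logged
  noise <- withr::with_seed(5, matrix(rnorm(20 * 15), 20, 15,
                                      dimnames = list(NULL, paste0("n", 1:15))))
  expect_message(pp4 <- fit_preprocess(noise, rep(c(1, 0), 10),
                                       f_alpha = 1e-6), "falling back")
  expect_length(pp4$genes, 10)
})

test_that("classification metrics match closed forms", {
  # perfect separation
  m <- classification_metrics(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(m["auc"]), 1)
  # confusion TP=40 TN=40 FP=10 FN=10: accuracy 0.8, kappa 0.6
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 10), rep(0.1, 40))
  labels <- c(rep(1, 50), rep(0, 50))
  m2 <- classification_metrics(scores, labels)
  expect_equal(unname(m2["accuracy"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m2["kappa"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(m2["precision"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m2["recall"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m2["f1"]), 0.8, tolerance = 1e-12)
  # AUC equals brute-force pair counting over random cases
  withr::with_seed(21, {
    for (rep in 1:25) {
      s <- round(runif(30), 2)  # ties included
      y <- rbinom(30, 1, 0.5)
      if (length(unique(y)) < 2) next
      pos <- s[y == 1]; neg <- s[y == 0]
      cmp <- outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b))
      expect_equal(unname(classification_metrics(s, y)["auc"]), mean(cmp),
                   tolerance = 1e-12)
    }
  })
})

test_that("cross-validation is stratified, seeded and leakage-guarded", {
  d <- toy_matrix()
  suite <- default_model_suite(ntree = 40)
  m1 <- crossval_evaluate(d$x, d$y, suite, k = 5, seed = 11)
  m2 <- crossval_evaluate(d$x, d$y, suite, k = 5, seed = 11)
  expect_equal(m1, m2)
  expect_true(all(m1$auc > 0.8))   # planted signal is separable
  expect_true(all(m1$auc >= 0 & m1$auc <= 1))
  expect_true(all(m1$kappa >= -1 & m1$kappa <= 1))
  expect_error(crossval_evaluate(d$x, rep(1, nrow(d$x)), suite),
               "single class")
  # k is lowered to the minimum class count with a message
  small <- toy_matrix(n = 12)
  suppressWarnings(   # glmnet grumbles at 6 observations per class
    expect_message(crossval_evaluate(small$x, small$y, suite["logistic"],
                                     k = 10, seed = 1),
                   "lowering fold count"))
})

test_that("composite_rank follows the documented tie arithmetic", {
  mk <- function(...) {
    v <- list(...)
    data.frame(model = names(v),
               do.call(rbind, lapply(v, function(r)
                 setNames(as.data.frame(t(r)),
                          c("auc", "accuracy", "f1", "precision", "recall",
                            "kappa")))),
               row.names = NULL)
  }
  # A best on all six -> 6 vs 12
  r1 <- composite_rank(mk(A = rep(0.9, 6), B = rep(0.8, 6)))
  expect_equal(setNames(r1$composite, r1$model), c(A = 6, B = 12))
  # identical -> both 9
  r2 <- composite_rank(mk(A = rep(0.9, 6), B = rep(0.9, 6)))
  expect_equal(r2$composite, c(9, 9))
  # better on one metric, tied on five -> 8.5 vs 9.5
  a <- rep(0.9, 6); b <- a; b[1] <- 0.8
  r3 <- composite_rank(mk(A = a, B = b))
  expect_equal(setNames(r3$composite, r3$model), c(A = 8.5, B = 9.5))
  # invariant to row order
  r4 <- composite_rank(mk(B = b, A = a))
  expect_equal(r4[order(r4$model), ], r3[order(r3$model), ],
               ignore_attr = TRUE)
})

test_that("importance extraction: intrinsic route and normalization", {
  stub <- ml_model("stub", fit = function(x, y) list(),
                   predict_score = function(m, x) rep(0.5, nrow(x)),
                   importance = function(m) c(2, 0, 0))
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  imp <- extract_importance(stub, stub$fit(x, NULL), x, rep(c(1, 0), 5))
  expect_equal(as.numeric(imp), c(1, 0, 0))
  expect_equal(attr(imp, "method"), "intrinsic")
  expect_equal(sum(imp), 1)
})

test_that("permutation fallback zeroes label-independent features", {
  d <- toy_matrix(n = 60, p = 4, shift_cols = 1, shift = 3, seed = 8)
  knn <- model_knn()
  fitted <- knn$fit(d$x, d$y)
  imp <- extract_importance(knn, fitted, d$x, d$y, n_perm = 20, seed = 2)
  expect_equal(attr(imp, "method"), "permutation")
  expect_gt(imp[["g1"]], 0.5)           # informative feature dominates
  expect_lt(max(imp[c("g3", "g4")]), 0.2)
  # duplicated informative feature: the pair jointly matters
  x2 <- cbind(d$x[, 1, drop = FALSE], dup = d$x[, 1], noise = d$x[, 4])
  f2 <- knn$fit(x2, d$y)
  imp2 <- extract_importance(knn, f2, x2, d$y, n_perm = 20, seed = 3)
  expect_gt(imp2[["g1"]] + imp2[["dup"]], imp2[["noise"]])
})

test_that("weighted_importance uses inverse-position weights", {
  v1 <- c(gA = 0.6, gB = 0.4)
  v2 <- c(gA = 0.3, gB = 0.7)
  agg <- weighted_importance(list(v1, v2))
  expect_equal(unname(agg["gA"]), (1 * 0.6 + 0.5 * 0.3) / 1.5)
  # one model -> identity
  expect_equal(weighted_importance(list(v1)), v1)
  # absent gene counts as zero
  v3 <- c(gC = 1)
  agg3 <- weighted_importance(list(v1, v3))
  expect_equal(unname(agg3["gC"]), (0.5 * 1) / 1.5)
})

test_that("evaluate_pathway returns a coherent bundle", {
  d <- toy_matrix(n = 40, p = 8, seed = 13)
  res <- evaluate_pathway(d$x, d$y, default_model_suite(ntree = 40), k = 4,
                          seed = 5, n_perm = 5)
  expect_s3_class(res$metrics, "model_metrics")
  expect_equal(sum(res$ranks$top), 5)
  expect_length(res$importances, 5)
  for (v in res$importances) expect_equal(sum(v), 1, tolerance = 1e-8)
})
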