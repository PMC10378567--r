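ft <- function(x, y) feature_table(as.matrix(x), y)

test_that("AdaBoost handles separable data and keeps weights normalized", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- rep(c("benign", "malignant"), each = 3)
  m <- adaboost_train(ft(x, y), T = 1L)
  expect_length(m$alphas, 1L)
  expect_gt(m$alphas[1], 10)             # eps clipped at 1e-10 -> large finite vote
  expect_true(is.finite(m$alphas[1]))
  expect_identical(as.character(adaboost_predict(m, x)), y)
  expect_error(adaboost_train(ft(x, rep("benign", 6))), "two classes")
})

test_that("AdaBoost weight updates renormalize to one each round", {
  set.seed(40)
  x <- matrix(rnorm(60), 30, 2)
  y <- ifelse(x[, 1] + 0.5 * rnorm(30) > 0, "malignant", "benign")
  if (length(unique(y)) == 1L) y[1] <- setdiff(c("benign", "malignant"), y[1])
  m <- adaboost_train(ft(x, y), T = 8L)
  expect_true(all(abs(m$weight_sums - 1) < 1e-12))
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  expect_true(all(m$weights > 0))
  # accepted rounds all beat chance
  expect_true(all(m$weighted_errors < 0.5))
  # alpha_t reproduces Eq-style vote weights from the stored errors
  eps_c <- pmin(pmax(m$weighted_errors, 1e-10), 1 - 1e-10)
  expect_equal(m$alphas, 0.5 * log((1 - eps_c) / eps_c))
})

test_that("boosted stumps beat the best single stump on XOR data", {
  set.seed(41)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             cbind(rnorm(20, 2, 0.2), rnorm(20, 2, 0.2)),
             cbind(rnorm(20, 0, 0.2), rnorm(20, 2, 0.2)),
             cbind(rnorm(20, 2, 0.2), rnorm(20, 0, 0.2)))
  y <- rep(c("benign", "benign", "malignant", "malignant"), each = 20)
  tab <- ft(x, y)
  single <- adaboost_train(tab, T = 1L)
  acc1 <- mean(adaboost_predict(single, x) == y)
  boosted <- adaboost_train(tab, T = 10L)
  accT <- mean(adaboost_predict(boosted, x) == y)
  expect_gt(accT, acc1)
  # training error non-increasing over rounds on this sample
  expect_lte(tail(boosted$train_errors, 1), boosted$train_errors[1])
})

test_that("prediction is the weighted vote with positive tie-break", {
  set.seed(42)
  x <- matrix(rnorm(40), 20, 2)
  y <- ifelse(x[, 1] > 0, "malignant", "benign")
  if (length(unique(y)) == 1L) y[1] <- "benign"
  m <- adaboost_train(ft(x, y), T = 5L)
  xt <- matrix(rnorm(40), 20, 2)
  # brute-force weighted vote oracle
  votes <- numeric(20)
  for (t in seq_along(m$weak_learners)) {
    s <- m$weak_learners[[t]]
    votes <- votes + m$alphas[t] * ifelse(xt[, s$feature] > s$threshold, 1, -1) * s$polarity
  }
  want <- ifelse(votes >= 0, "malignant", "benign")
  expect_identical(as.character(adaboost_predict(m, xt)), want)
  expect_equal(adaboost_predict(m, xt, type = "score"), votes)
  # negating alphas flips every non-tied prediction
  m2 <- m; m2$alphas <- -m$alphas
  s2 <- adaboost_predict(m2, xt, type = "score")
  nz <- abs(votes) > 1e-12
  expect_true(all(sign(s2[nz]) == -sign(votes[nz])))
  # single learner: predictions equal that stump's
  m1 <- adaboost_train(ft(x, y), T = 1L)
  s <- m1$weak_learners[[1]]
  expect_identical(as.character(adaboost_predict(m1, xt)),
                   ifelse(ifelse(xt[, s$feature] > s$threshold, 1, -1) * s$polarity > 0,
                          "malignant", "benign"))
})

test_that("evaluation metrics match direct formulas on all small matrices", {
  for (tp in 0:2) for (tn in 0:2) for (fp in 0:2) for (fn in 0:2) {
    n <- tp + tn + fp + fn
    if (n == 0) next
    y_true <- c(rep("malignant", tp + fn), rep("benign", tn + fp))
    y_pred <- c(rep("malignant", tp), rep("benign", fn),
                rep("benign", tn), rep("malignant", fp))
    rep_ <- suppressWarnings(evaluate_predictions(y_true, y_pred))
    expect_identical(unlist(rep_$confusion), c(tp = tp, tn = tn, fp = fp, fn = fn))
    expect_equal(rep_$accuracy, (tp + tn) / n)
    sen <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spe <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    pre <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    expect_equal(rep_$sensitivity, sen)
    expect_equal(rep_$specificity, spe)
    expect_equal(rep_$precision, pre)
    f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
      2 * pre * sen / (pre + sen)
    expect_equal(rep_$f1, f1)
    expect_equal(rep_$iba, (1 + 0.1 * (sen - spe)) * sen * spe)
  }
})

test_that("IBA reduces to Recall * Specificity at zero dominance", {
  # perfect prediction
  y <- rep(c("benign", "malignant"), each = 5)
  r <- evaluate_predictions(y, y)
  expect_identical(r$iba, 1)
  expect_identical(r$accuracy, 1)
  # recall = specificity = 0.96 prints as IBA 92%
  y_true <- rep(c("malignant", "benign"), each = 100)
  y_pred <- c(rep("malignant", 96), rep("benign", 4),
              rep("benign", 96), rep("malignant", 4))
  r2 <- evaluate_predictions(y_true, y_pred)
  expect_equal(r2$iba, 0.96 * 0.96)
  expect_identical(round(100 * r2$iba), 92)
  # balanced 1/1/1/1 matrix
  r3 <- evaluate_predictions(c("malignant", "malignant", "benign", "benign"),
                             c("malignant", "benign", "benign", "malignant"))
  expect_equal(unlist(r3[c("accuracy", "precision", "sensitivity", "f1")]),
               c(accuracy = 0.5, precision = 0.5, sensitivity = 0.5, f1 = 0.5))
  # macro row averages the two per-class views
  expect_equal(r2$per_class["macro", "accuracy"],
               mean(r2$per_class[c("benign", "malignant"), "accuracy"]))
})

test_that("undefined metrics surface as flagged NA, not silent zeros", {
  w <- testthat::capture_warnings(
    r <- evaluate_predictions(rep("benign", 4), rep("benign", 4)))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(r$sensitivity))
  expect_identical(r$specificity, 1)
  expect_error(evaluate_predictions(character(0), character(0)), "empty")
})

test_that("rank-sum test agrees with exhaustive permutation at small n", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(w$W, 6)
  # brute force over all C(6,3) rank assignments
  combs <- combn(6, 3)
  sums <- colSums(matrix((1:6)[combs], nrow = 3))
  p_exact <- mean(abs(sums - 10.5) >= abs(6 - 10.5))
  expect_equal(w$p_value, p_exact)
  expect_false(w$reject)  # 0.1 > 0.05
  # all group sizes <= 5: exact enumeration equality
  set.seed(43)
  for (na in 2:5) for (nb in 2:5) {
    a <- rnorm(na); b <- rnorm(nb)
    res <- wilcoxon_rank_sum(a, b)
    r <- rank(c(a, b)); W <- sum(r[seq_len(na)])
    cmb <- combn(na + nb, na)
    sums <- colSums(matrix(seq_len(na + nb)[cmb], nrow = na))
    mu <- na * (na + nb + 1) / 2
    expect_equal(res$p_value, mean(abs(sums - mu) >= abs(W - mu) - 1e-9))
  }
  # identical samples: no rejection
  expect_false(wilcoxon_rank_sum(1:8, 1:8)$reject)
})

test_that("rank-sum type-I error sits near the nominal level", {
  set.seed(44)
  rej <- replicate(1000, wilcoxon_rank_sum(rnorm(30), rnorm(30))$reject)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("all three classifier adapters satisfy the common contract", {
  tab <- make_planted_feature_table(
    planted_spec(120L, 8L, informative_indices = c(1L, 5L), effect_size = 3,
                 seed = 45))
  sp <- stratified_split(tab, 0.75, seed = 3L)
  for (nm in c("xgboost", "adaboost_native", "mlp")) {
    ad <- classifier_adapter(nm, seed = 11L)
    fit <- ad$fit(sp$train)
    pred <- fit$predict(sp$test$values)
    expect_length(pred, nrow(sp$test$values))
    acc <- mean(pred == sp$test$labels)
    expect_gt(acc, 0.9)
    # seeded determinism
    pred2 <- classifier_adapter(nm, seed = 11L)$fit(sp$train)$predict(sp$test$values)
    expect_identical(pred, pred2)
  }
  expect_error(classifier_adapter("svm"), "valid names")
})
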