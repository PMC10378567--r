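# Exhaustive weighted decision stump: best (feature, threshold, polarity)
# minimizing weighted 0/1 error. Ties resolve to the first candidate in
# feature-then-threshold order, keeping training deterministic.
fit_stump <- function(x, y, w) {
  n <- nrow(x); p <- ncol(x)
  best <- list(err = Inf)
  total_pos <- sum(w[y == 1])
  for (j in seq_len(p)) {
    o <- order(x[, j])
    xs <- x[o, j]; ys <- y[o]; ws <- w[o]
    # cumulative weight of positives/negatives at or below each split point
    cum_pos <- cumsum(ws * (ys == 1))
    cum_neg <- cumsum(ws * (ys == -1))
    distinct <- which(diff(xs) > 0)
    # candidate thresholds between consecutive distinct values, plus the
    # degenerate all-on-one-side stump via threshold below the minimum
    cand <- c(0L, distinct)
    for (ci in cand) {
      below_pos <- if (ci == 0L) 0 else cum_pos[ci]
      below_neg <- if (ci == 0L) 0 else cum_neg[ci]
      # polarity +1: predict +1 above the threshold
      err_up <- below_pos + (sum(w) - total_pos - below_neg)
      err_dn <- sum(w) - err_up
      thr <- if (ci == 0L) xs[1L] - 1 else (xs[ci] + xs[ci + 1L]) / 2
      if (err_up < best$err - 1e-15) {
        best <- list(feature = j, threshold = thr, polarity = 1, err = err_up)
      }
      if (err_dn < best$err - 1e-15) {
        best <- list(feature = j, threshold = thr, polarity = -1, err = err_dn)
      }
    }
  }
  best
}

predict_stump <- function(stump, x) {
  s <- ifelse(x[, stump$feature] > stump$threshold, 1, -1)
  s * stump$polarity
}

#' Train an AdaBoost ensemble of decision stumps
#'
#' The classical discrete AdaBoost recurrence: sample weights start uniform
#' at 1/N; each round fits a depth-1 decision tree (stump) to the weighted
#' sample, computes its weighted error eps_t, sets its vote
#' alpha_t = 0.5 log((1 - eps_t)/eps_t), and reweights samples by
#' exp(-alpha_t y_i h_t(x_i)) normalized to sum 1. eps_t is clipped to
#' \[1e-10, 1 - 1e-10\] before the log so alpha_t stays finite; boosting
#' stops early when eps_t is 0 (perfect learner kept) or >= 0.5.
#'
#' @param table A [feature_table()] with two classes (benign -> -1,
#'   malignant -> +1), or a list with `values` and `labels`.
#' @param T Maximum boosting rounds.
#' @param seed Unused by the deterministic stump learner; kept so the
#'   classifier contract is uniform.
#' @return An `adaboost_model` with `weak_learners`, `alphas`, `T`,
#'   `levels`, and per-round `train_errors` of the ensemble.
#' @export
adaboost_train <- function(table, T = 50L, seed = 1L) {
  x <- as.matrix(table$values)
  lv <- levels(droplevels(factor(table$labels)))
  if (length(lv) != 2L) stop("AdaBoost requires exactly two classes")
  y <- ifelse(as.character(table$labels) == lv[2L], 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0); tr_err <- numeric(0)
  errors <- numeric(0); weight_sums <- numeric(0)
  agg <- numeric(n)
  for (t in seq_len(T)) {
    st <- fit_stump(x, y, w)
    h <- predict_stump(st, x)
    eps <- sum(w * (h != y))
    if (eps >= 0.5) break
    eps_c <- min(max(eps, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    learners[[length(learners) + 1L]] <- st
    alphas <- c(alphas, alpha)
    errors <- c(errors, eps)
    agg <- agg + alpha * h
    tr_err <- c(tr_err, mean(sign(agg) * y <= 0))
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    weight_sums <- c(weight_sums, sum(w))
    if (eps == 0) break
  }
  if (length(learners) == 0L) stop("no weak learner beat chance")
  structure(list(weak_learners = learners, alphas = alphas,
                 T = as.integer(T), levels = lv, train_errors = tr_err,
                 weighted_errors = errors, weight_sums = weight_sums,
                 weights = w),
            class = "adaboost_model")
}

#' Predict with an AdaBoost ensemble
#'
#' The strong classifier sign(sum_t alpha_t h_t(x)); an exact zero vote is
#' resolved to the positive (malignant) class.
#'
#' @param model An `adaboost_model`.
#' @param x Feature matrix with the training feature count.
#' @param type `"class"` for labels, `"score"` for the raw weighted vote.
#' @return Factor of predicted labels, or numeric scores.
#' @export
adaboost_predict <- function(model, x, type = c("class", "score")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  need <- max(vapply(model$weak_learners, function(s) s$feature, integer(1)))
  if (ncol(x) < need) stop("feature count does not match the trained model")
  score <- numeric(nrow(x))
  for (t in seq_along(model$weak_learners))
    score <- score + model$alphas[t] * predict_stump(model$weak_learners[[t]], x)
  if (type == "score") return(score)
  factor(ifelse(score >= 0, model$levels[2L], model$levels[1L]),
         levels = model$levels)
}

#' Uniform classifier contract over XGBoost, native AdaBoost, and MLP
#'
#' Returns a list with `name`, `fit(table)` and, from the fitted object,
#' `predict(x)`. `"xgboost"` and `"mlp"` delegate to the xgboost and nnet
#' packages with seeded, single-threaded determinism; `"adaboost_native"`
#' is this package's implementation.
#'
#' @param name One of `"xgboost"`, `"adaboost_native"`, `"mlp"`.
#' @param params Optional list of hyperparameters (`nrounds`, `max_depth`
#'   for xgboost; `T` for adaboost; `size`, `decay`, `maxit` for mlp).
#' @param seed Integer seed.
#' @return A `classifier_adapter` list with `name` and `fit`; `fit` returns
#'   an object with a `predict(x)` closure returning a label factor.
#' @export
classifier_adapter <- function(name, params = list(), seed = 1L) {
  valid <- c("xgboost", "adaboost_native", "mlp")
  if (!name %in% valid)
    stop("unknown classifier '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  fit <- switch(
    name,
    xgboost = function(table) {
      lv <- levels(droplevels(table$labels))
      yf <- factor(as.character(table$labels), levels = lv)
      bst <- xgboost::xgboost(
        as.matrix(table$values), yf,
        objective = "binary:logistic",
        nrounds = params$nrounds %||% 100L,
        max_depth = params$max_depth %||% 4L,
        learning_rate = 0.3, nthreads = 1L, verbosity = 0L, seed = seed)
      list(predict = function(x) {
        pr <- predict(bst, as.matrix(x))   # P(second factor level)
        factor(ifelse(pr > 0.5, lv[2L], lv[1L]), levels = lv)
      })
    },
    adaboost_native = function(table) {
      model <- adaboost_train(table, T = params$T %||% 50L, seed = seed)
      list(predict = function(x) adaboost_predict(model, x), model = model)
    },
    mlp = function(table) {
      lv <- levels(droplevels(table$labels))
      x <- scale(as.matrix(table$values))
      ctr <- attr(x, "scaled:center"); scl <- attr(x, "scaled:scale")
      scl[scl == 0 | !is.finite(scl)] <- 1
      x[!is.finite(x)] <- 0
      yv <- as.integer(as.character(table$labels) == lv[2L])
      net <- with_seed(seed, nnet::nnet(
        x, yv, size = params$size %||% 16L, decay = params$decay %||% 1e-3,
        maxit = params$maxit %||% 300L, entropy = TRUE, trace = FALSE,
        MaxNWts = 1e6))
      list(predict = function(xnew) {
        xn <- sweep(sweep(as.matrix(xnew), 2L, ctr), 2L, scl, "/")
        xn[!is.finite(xn)] <- 0
        pr <- predict(net, xn)
        factor(ifelse(pr > 0.5, lv[2L], lv[1L]), levels = lv)
      })
    })
  structure(list(name = name, fit = fit), class = "classifier_adapter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
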