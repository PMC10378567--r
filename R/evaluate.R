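#' Confusion matrix with malignant as the positive class
#'
#' @param y_true,y_pred Vectors/factors of `"benign"`/`"malignant"` labels,
#'   equal length.
#' @return List of counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  t_pos <- as.character(y_true) == "malignant"
  p_pos <- as.character(y_pred) == "malignant"
  list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
       fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

# A single class's metric set from confusion counts; zero denominators
# yield NA ("undefined") with a warning rather than silent zeros.
metrics_from_counts <- function(tp, tn, fp, fn, alpha = 0.1) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- safe(tp + tn, tp + tn + fp + fn, "accuracy")
  sen <- safe(tp, tp + fn, "sensitivity")
  spe <- safe(tn, tn + fp, "specificity")
  pre <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(pre) || is.na(sen) || (pre + sen) == 0) {
    warning("f1 undefined (zero denominator)", call. = FALSE)
    NA_real_
  } else 2 * pre * sen / (pre + sen)
  dom <- sen - spe
  iba <- (1 + alpha * dom) * (sen * spe)
  list(accuracy = acc, sensitivity = sen, specificity = spe,
       precision = pre, f1 = f1, dominance = dom, iba = iba)
}

#' Evaluate binary lesion predictions
#'
#' Builds the confusion matrix (malignant = positive) and reports accuracy,
#' sensitivity (recall), specificity, precision, F1, Dominance
#' (Recall - Specificity) and the Index Balanced Accuracy
#' IBA = (1 + alpha * Dominance) * (Recall * Specificity), per class and
#' macro-averaged. Per-class rows treat each class in turn as positive.
#' Metrics with zero denominators are reported as NA with a warning.
#'
#' @param y_true,y_pred Label vectors (`"benign"`/`"malignant"`).
#' @param alpha IBA dominance weight (default 0.1).
#' @return An `evaluation_report`: list with `confusion`, `per_class`
#'   (data frame, rows benign/malignant/macro), and top-level metrics for
#'   the malignant-positive view.
#' @export
evaluate_predictions <- function(y_true, y_pred, alpha = 0.1) {
  cm <- confusion_counts(y_true, y_pred)
  pos <- metrics_from_counts(cm$tp, cm$tn, cm$fp, cm$fn, alpha)
  # benign as positive class = swapped counts
  neg <- metrics_from_counts(cm$tn, cm$tp, cm$fn, cm$fp, alpha)
  per_class <- rbind(as.data.frame(neg), as.data.frame(pos))
  macro <- colMeans(per_class, na.rm = FALSE)
  per_class <- rbind(per_class, macro)
  rownames(per_class) <- c("benign", "malignant", "macro")
  structure(c(list(confusion = cm, per_class = per_class, alpha = alpha),
              pos),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("confusion (malignant positive): tp=%d tn=%d fp=%d fn=%d\n",
              cm$tp, cm$tn, cm$fp, cm$fn))
  print(round(x$per_class, 4))
  invisible(x)
}

#' Wilcoxon rank-sum test of two independent groups
#'
#' Pools both groups, assigns midranks, and takes W as the rank sum of
#' group A. For small untied samples (combined n <= 10) the two-sided
#' p-value is computed by exhaustive enumeration of all rank assignments;
#' otherwise it comes from the normal approximation with tie-corrected
#' variance and continuity correction. The decision rejects the null at
#' alpha = 0.05.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param alpha Significance level for the reported decision.
#' @return List with `W`, `p_value`, `reject` (logical), `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, alpha = 0.05) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  ties <- any(duplicated(pooled))
  if (n <= 10L && !ties) {
    # exhaustive: distribution of the rank sum over all C(n, na) subsets
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(seq_len(n)[combs], nrow = na))
    mu <- na * (n + 1) / 2
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- na * (n + 1) / 2
    tie_tab <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  p <- min(1, p)
  list(W = W, p_value = p, reject = p < alpha, method = method)
}
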