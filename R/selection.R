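#' Feature table container
#'
#' The currency of the selection and classification stages: a numeric
#' matrix of samples x named features with an aligned benign/malignant
#' label factor.
#'
#' @param values Numeric matrix (samples in rows) with unique column names;
#'   missing values are not allowed.
#' @param labels Vector or factor of class labels, one per row.
#' @return An object of class `feature_table` with `values`, `labels`,
#'   `column_names`.
#' @export
feature_table <- function(values, labels) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature values must not contain missing values")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) stop("column names must be unique")
  if (length(labels) != nrow(values))
    stop("labels length must equal the sample count")
  labels <- factor(labels, levels = union(c("benign", "malignant"),
                                          unique(as.character(labels))))
  labels <- droplevels(labels)
  structure(list(values = values, labels = labels,
                 column_names = colnames(values)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table %d samples x %d features; labels: %s>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# 5-fold (or k-fold) CV accuracy of a decision tree restricted to `cols`.
# Folds are assigned deterministically from the RNG state of the caller.
tree_cv_accuracy <- function(table, cols, folds) {
  if (length(cols) == 0L) return(0)
  x <- table$values[, cols, drop = FALSE]
  y <- table$labels
  k <- max(folds)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    # matrix-formula interface: avoids per-fit model.frame cost on wide data
    fit <- rpart::rpart(y ~ x, data = list(y = y[tr], x = x[tr, , drop = FALSE]),
                        method = "class",
                        control = rpart::rpart.control(xval = 0L, cp = 0.01))
    pred <- predict(fit, list(x = x[!tr, , drop = FALSE]), type = "class")
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Genetic-algorithm configuration
#'
#' @param population_size Initial population size (default 500).
#' @param crossover_fraction Fraction of genes exchanged at crossover
#'   (default 0.5: the offspring takes the first half of one parent and the
#'   second half of the other, split at the midpoint).
#' @param mutation_rate Per-gene flip probability (default 0.05).
#' @param mu Survivors kept each generation (default 50).
#' @param lambda Offspring produced each generation (default 100).
#' @param max_generations Generation cap (default 35).
#' @param patience Generations without best-fitness improvement before
#'   stopping (default 5).
#' @param cv_folds Cross-validation folds for the decision-tree fitness
#'   (default 5).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @export
ga_config <- function(population_size = 500L, crossover_fraction = 0.5,
                      mutation_rate = 0.05, mu = 50L, lambda = 100L,
                      max_generations = 35L, patience = 5L, cv_folds = 5L,
                      seed = 1L) {
  stopifnot(population_size >= 2L, crossover_fraction > 0,
            crossover_fraction < 1, mutation_rate >= 0, mutation_rate <= 1,
            cv_folds >= 2L, mu >= 1L, lambda >= 1L)
  list(population_size = as.integer(population_size),
       crossover_fraction = crossover_fraction,
       mutation_rate = mutation_rate, mu = as.integer(mu),
       lambda = as.integer(lambda),
       max_generations = as.integer(max_generations),
       patience = as.integer(patience), cv_folds = as.integer(cv_folds),
       seed = as.integer(seed))
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary gene strings over the feature columns. Fitness of an
#' individual is the mean k-fold cross-validated accuracy of a decision
#' tree trained on its selected columns (0 for the empty individual). Each
#' generation, the mu fittest individuals survive; lambda offspring are
#' produced by midpoint crossover of two random survivors followed by
#' independent per-gene mutation, and survivors and offspring compete
#' jointly (mu + lambda selection, so the best fitness never decreases).
#' The run stops at `max_generations` or after `patience` generations
#' without improvement.
#'
#' @param table A [feature_table()] with both classes present.
#' @param config A [ga_config()].
#' @return A `selection_mask` list: `keep` (logical over columns), `scores`
#'   (per-column inclusion frequency in the final population), `method`
#'   ("GA"), `best_fitness`, `fitness_history`.
#' @export
ga_select <- function(table, config = ga_config()) {
  stopifnot(inherits(table, "feature_table"))
  p <- ncol(table$values)
  if (p < 1L) stop("need at least one feature")
  if (nlevels(droplevels(table$labels)) < 2L)
    stop("both classes must be present")
  n <- nrow(table$values)
  with_seed(config$seed, {
    folds <- sample(rep_len(seq_len(config$cv_folds), n))
    fitness <- function(genes)
      tree_cv_accuracy(table, which(genes), folds)
    pop <- matrix(stats::runif(config$population_size * p) < 0.5,
                  config$population_size, p)
    if (p == 1L) pop[, 1L] <- TRUE
    fit <- apply(pop, 1L, fitness)
    ord <- order(fit, decreasing = TRUE)
    mu <- min(config$mu, nrow(pop))
    pop <- pop[ord[seq_len(mu)], , drop = FALSE]
    fit <- fit[ord[seq_len(mu)]]
    history <- fit[1L]
    stall <- 0L
    for (gen in seq_len(config$max_generations)) {
      cut <- max(1L, round(p * config$crossover_fraction))
      kids <- matrix(FALSE, config$lambda, p)
      for (i in seq_len(config$lambda)) {
        pa <- sample.int(mu, 2L, replace = mu < 2L)
        child <- c(pop[pa[1L], seq_len(cut)],
                   if (cut < p) pop[pa[2L], (cut + 1L):p])
        flip <- stats::runif(p) < config$mutation_rate
        kids[i, ] <- xor(child, flip)
      }
      kfit <- apply(kids, 1L, fitness)
      all_pop <- rbind(pop, kids)
      all_fit <- c(fit, kfit)
      ord <- order(all_fit, decreasing = TRUE)
      pop <- all_pop[ord[seq_len(mu)], , drop = FALSE]
      fit <- all_fit[ord[seq_len(mu)]]
      improved <- fit[1L] > history[length(history)] + 1e-12
      history <- c(history, fit[1L])
      stall <- if (improved) 0L else stall + 1L
      if (stall >= config$patience) break
    }
    structure(list(keep = pop[1L, ], scores = colMeans(pop),
                   method = "GA", best_fitness = fit[1L],
                   fitness_history = history),
              class = "selection_mask")
  })
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask [%s]: %d of %d features kept>\n",
              x$method, sum(x$keep), length(x$keep)))
  invisible(x)
}

# Count, per sample, the points of `xo` (sorted) strictly within radius[i]
# of x[i], self included. Candidate windows come from binary search; the
# strict comparison is done on exact distances so boundary points (the k-th
# neighbor itself) are never miscounted through rounding.
count_within <- function(x, xo, radius) {
  n <- length(x)
  lo <- findInterval(x - radius, xo)
  hi <- findInterval(x + radius, xo) + 1L
  out <- integer(n)
  nn <- length(xo)
  for (i in seq_len(n)) {
    a <- max(1L, lo[i]); b <- min(nn, hi[i])
    out[i] <- sum(abs(xo[a:b] - x[i]) < radius[i])
  }
  out
}

# Kraskov-style kNN estimate of I(X;Y) for a continuous feature x and a
# discrete label y (mixed-variable variant): for sample i, take the
# Chebyshev distance to its k-th neighbor among same-class samples, count
# the neighbors m_i within that distance in the pooled sample, and combine
# digamma terms. For scalar features the Chebyshev norm is |x_i - x_j| and
# both searches reduce to sorted-vector lookups.
mi_mixed_discrete <- function(x, y, k) {
  n <- length(x)
  classes <- levels(y)
  dist_k <- numeric(n)
  for (cl in classes) {
    id <- which(y == cl)
    xs <- x[id]
    o <- order(xs)
    xs <- xs[o]
    nc <- length(xs)
    kk <- min(k, nc - 1L)
    if (kk < 1L) return(0)
    d <- numeric(nc)
    for (j in seq_len(nc)) {
      lo <- max(1L, j - kk); hi <- min(nc, j + kk)
      cand <- abs(xs[lo:hi] - xs[j])
      d[j] <- sort(cand, partial = kk + 1L)[kk + 1L]  # skip self (distance 0)
    }
    dist_k[id[o]] <- d
  }
  xo <- sort(x)
  # m_i: pooled points strictly within the same-class k-th neighbor distance
  # (ties at exactly that radius excluded), self removed
  m <- count_within(x, xo, dist_k) - 1L
  m[m < 1L] <- 1L
  n_class <- as.vector(table(y)[as.character(y)])
  val <- digamma(n) - mean(digamma(n_class)) + digamma(k) -
    mean(digamma(m + 1L))
  max(0, val)
}

#' Mutual information of each feature with the class label
#'
#' Estimates, per feature, the mutual information between the continuous
#' feature values and the discrete benign/malignant label using the
#' k-nearest-neighbor (Chebyshev-distance) estimator in its mixed
#' continuous-discrete form. Negative estimates are clamped to zero;
#' constant features score zero. A tiny seeded jitter breaks exact ties.
#'
#' @param table A [feature_table()].
#' @param k Neighbor count (default 3).
#' @param jitter_seed Seed for the tie-breaking jitter.
#' @return A `selection_mask` with `scores` only (`keep` all FALSE until a
#'   cut is applied via [select_top_k()]).
#' @export
mi_scores <- function(table, k = 3L, jitter_seed = 1L) {
  stopifnot(inherits(table, "feature_table"), k >= 1L)
  if (k >= min(table(table$labels)))
    stop("`k` must be smaller than the per-class sample count")
  x <- table$values
  y <- droplevels(table$labels)
  scores <- with_seed(jitter_seed, {
    vapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      s <- stats::sd(v)
      if (s == 0) return(0)
      v <- v + stats::rnorm(length(v), sd = s * 1e-10)
      mi_mixed_discrete(v, y, k)
    }, numeric(1))
  })
  names(scores) <- colnames(x)
  structure(list(keep = rep(FALSE, ncol(x)), scores = scores, method = "MI"),
            class = "selection_mask")
}

#' Kraskov kNN mutual information between two continuous variables
#'
#' The estimator core used for validation against closed forms: for each
#' point, the Chebyshev distance to its k-th joint-space neighbor defines a
#' radius; marginal neighbor counts within that radius enter a digamma
#' average. For bivariate Gaussians with correlation rho the truth is
#' -0.5 log(1 - rho^2).
#'
#' @param x,y Numeric vectors of equal length.
#' @param k Neighbor count (default 3).
#' @return Estimated mutual information in nats (clamped at 0).
#' @export
ksg_mi <- function(x, y, k = 3L) {
  n <- length(x)
  stopifnot(length(y) == n, k >= 1L, k < n)
  dist_k <- numeric(n)
  for (i in seq_len(n)) {
    d <- pmax(abs(x - x[i]), abs(y - y[i]))
    dist_k[i] <- sort(d, partial = k + 1L)[k + 1L]
  }
  xo <- sort(x); yo <- sort(y)
  nx <- count_within(x, xo, dist_k) - 1L
  ny <- count_within(y, yo, dist_k) - 1L
  nx[nx < 1L] <- 1L; ny[ny < 1L] <- 1L
  max(0, digamma(k) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L)))
}

#' Keep the k highest-scoring features
#'
#' Ties are broken in favor of the lower column index.
#'
#' @param scores A `selection_mask` with scores, or a named numeric vector.
#' @param k Number of features to keep (default 26).
#' @return A `selection_mask` with `keep` set.
#' @export
select_top_k <- function(scores, k = 26L) {
  sc <- if (inherits(scores, "selection_mask")) scores$scores else scores
  if (k > length(sc)) stop("`k` exceeds the feature count")
  ord <- order(-sc, seq_along(sc))
  keep <- rep(FALSE, length(sc))
  keep[ord[seq_len(k)]] <- TRUE
  method <- if (inherits(scores, "selection_mask")) scores$method else "MI"
  structure(list(keep = keep, scores = sc, method = method),
            class = "selection_mask")
}

#' Fuse genetic-algorithm and mutual-information selections
#'
#' Concatenates the GA-selected columns followed by the MI-selected
#' columns. Features selected by both methods appear twice (plain
#' concatenation); names are suffixed with the method to stay unique.
#'
#' @param table The [feature_table()] both masks refer to.
#' @param ga,mi `selection_mask` objects over the same columns.
#' @return A [feature_table()] with `sum(ga$keep) + sum(mi$keep)` columns.
#' @export
fuse_selections <- function(table, ga, mi) {
  stopifnot(inherits(table, "feature_table"))
  p <- ncol(table$values)
  if (length(ga$keep) != p || length(mi$keep) != p)
    stop("selection mask length does not match the table")
  ga_cols <- which(ga$keep); mi_cols <- which(mi$keep)
  vals <- cbind(table$values[, ga_cols, drop = FALSE],
                table$values[, mi_cols, drop = FALSE])
  colnames(vals) <- c(paste0(colnames(table$values)[ga_cols], "_GA"),
                      paste0(colnames(table$values)[mi_cols], "_MI"))
  feature_table(vals, table$labels)
}

#' Random undersampling to the minority-class count
#'
#' Every class is downsampled without replacement to the size of the
#' smallest class, and the retained rows are shuffled, all deterministically
#' from `seed`.
#'
#' @param table A [feature_table()] with at least two classes.
#' @param seed Integer seed.
#' @return A balanced [feature_table()] whose rows are a subset of the
#'   input rows.
#' @export
random_undersample <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  y <- droplevels(table$labels)
  if (nlevels(y) < 2L) stop("need at least two non-empty classes")
  n_min <- min(table(y))
  with_seed(seed, {
    keep <- unlist(lapply(levels(y), function(cl) {
      id <- which(y == cl)
      if (length(id) > n_min) sample(id, n_min) else id
    }))
    keep <- sample(keep)
    feature_table(table$values[keep, , drop = FALSE], y[keep])
  })
}
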