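#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All seeds are recorded in
#' the run's evaluation report, so identical manifest + config reproduce
#' identical output.
#'
#' @param segmentation A [segment_config()].
#' @param input_size Descriptor input side for texture features.
#' @param pca_components Texture PCA components to retain (default 199,
#'   capped at the rank of the texture matrix).
#' @param deep_dim,deep_seed Stub deep-extractor width (default 1920) and
#'   projection seed.
#' @param deep_name `"stub"` or `"densenet201"`.
#' @param ga A [ga_config()].
#' @param mi_k Neighbor count of the MI estimator (default 3).
#' @param mi_top_k MI features kept (default 26).
#' @param rus_seed Random-undersampling seed.
#' @param split_fraction Training fraction of the stratified split
#'   (default 0.8).
#' @param split_seed Split seed.
#' @param classifier `"xgboost"`, `"adaboost_native"` or `"mlp"`.
#' @param classifier_params,classifier_seed Adapter hyperparameters / seed.
#' @param pair_seed Seed of the random within-class pairing used when two
#'   modalities are fused into one row per sample pair.
#' @export
pipeline_config <- function(segmentation = segment_config(),
                            input_size = 128L, pca_components = 199L,
                            deep_dim = 1920L, deep_seed = 42L,
                            deep_name = "stub",
                            ga = ga_config(population_size = 40L, mu = 15L,
                                           lambda = 30L, max_generations = 10L,
                                           patience = 4L),
                            mi_k = 3L, mi_top_k = 26L, rus_seed = 7L,
                            split_fraction = 0.8, split_seed = 11L,
                            classifier = "xgboost",
                            classifier_params = list(),
                            classifier_seed = 13L, pair_seed = 17L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  list(segmentation = segmentation, input_size = as.integer(input_size),
       pca_components = as.integer(pca_components),
       deep_dim = as.integer(deep_dim), deep_seed = as.integer(deep_seed),
       deep_name = deep_name, ga = ga, mi_k = as.integer(mi_k),
       mi_top_k = as.integer(mi_top_k), rus_seed = as.integer(rus_seed),
       split_fraction = split_fraction, split_seed = as.integer(split_seed),
       classifier = classifier, classifier_params = classifier_params,
       classifier_seed = as.integer(classifier_seed),
       pair_seed = as.integer(pair_seed))
}

#' Per-sample hybrid features for one modality
#'
#' For each manifest row: obtains the lesion mask and ROI (from the
#' provided mask when `mask_path` is set, mirroring manually delineated
#' ultrasound ROIs; otherwise by [segment_lesion()]), then extracts deep
#' features, the HOG+LBP texture vector, and the four shape features.
#' Texture vectors of all samples are PCA-reduced jointly. Columns are
#' ordered deep, then PCA texture (`HUfeature*`), then shape, so selection
#' outputs refer to stable indices.
#'
#' @param manifest Data frame with columns `path`, `mask_path` (may be
#'   empty/NA), `modality`, `label`.
#' @param config A [pipeline_config()].
#' @return A list with `table` (a [feature_table()] of width
#'   `deep_dim + pca_components + 4`) and the fitted `pca` model.
#' @export
build_feature_table <- function(manifest, config = pipeline_config()) {
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest")
  extractor <- deep_extractor(config$deep_name, dim = config$deep_dim,
                              seed = config$deep_seed)
  deep <- matrix(NA_real_, n, extractor$output_dim)
  tex <- NULL
  shape <- matrix(NA_real_, n, 4L,
                  dimnames = list(NULL, c("Area", "Perimeter",
                                          "Eccentricity", "Circularity")))
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    img <- read_gray_png(row$path)
    res <- tryCatch({
      mp <- row$mask_path
      if (!is.null(mp) && !is.na(mp) && nzchar(mp)) {
        mask <- read_mask_png(mp)
        cs <- trace_contours(mask)
        if (length(cs) == 0L) stop("provided mask is empty")
        best <- largest_lesion(cs, mask)
        box <- bounding_box(best$contour, config$segmentation$tolerance,
                            dim(mask))
        list(mask = best$mask, roi = gray_image(crop_box(img, box)),
             contour = best$contour)
      } else {
        segment_lesion(img, config$segmentation)
      }
    }, error = function(e) {
      stop(sprintf("stage 'segment' failed for sample '%s': %s",
                   row$path, conditionMessage(e)), call. = FALSE)
    })
    deep[i, ] <- extractor$extract(res$roi)
    tv <- texture_vector(res$roi, input_size = config$input_size)
    if (is.null(tex)) tex <- matrix(NA_real_, n, length(tv),
                                    dimnames = list(NULL, names(tv)))
    tex[i, ] <- tv
    sf <- shape_features(res$mask, res$contour)
    shape[i, ] <- c(sf$area, sf$perimeter, sf$eccentricity, sf$circularity)
  }
  pca <- pca_fit(tex, config$pca_components)
  hu <- pca_transform(pca, tex)
  colnames(hu) <- paste0("HUfeature", seq_len(ncol(hu)) - 1L)
  colnames(deep) <- paste0("Featuredeep", seq_len(ncol(deep)) - 1L)
  values <- cbind(deep, hu, shape)
  list(table = feature_table(values, manifest$label), pca = pca)
}

#' Stratified train/test split
#'
#' Splits each class proportionally: the test set takes
#' floor(n_class * (1 - fraction)) samples per class, the remainder trains;
#' assignment is a seeded shuffle. Train and test are disjoint and jointly
#' exhaustive.
#'
#' @param table A [feature_table()].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables and the row index
#'   vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(table, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  y <- droplevels(table$labels)
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  with_seed(seed, {
    test_idx <- integer(0)
    for (cl in levels(y)) {
      id <- which(y == cl)
      # tolerance guards floor against 0.2 * n landing at 41.999...
      n_test <- floor(length(id) * (1 - fraction) + 1e-9)
      test_idx <- c(test_idx, sample(id, n_test))
    }
    train_idx <- setdiff(seq_along(y), test_idx)
    train_idx <- sample(train_idx); test_idx <- sample(test_idx)
    list(train = feature_table(table$values[train_idx, , drop = FALSE],
                               y[train_idx]),
         test = feature_table(table$values[test_idx, , drop = FALSE],
                              y[test_idx]),
         train_idx = train_idx, test_idx = test_idx)
  })
}

# Random seeded within-class pairing of two modality tables into rows of
# concatenated width. The pairing rule is an interpretation: samples of the
# same class are matched uniformly at random under pair_seed.
pair_modalities <- function(tables, seed) {
  stopifnot(length(tables) == 2L)
  a <- tables[[1L]]; b <- tables[[2L]]
  with_seed(seed, {
    rows_a <- integer(0); rows_b <- integer(0); labs <- character(0)
    for (cl in intersect(levels(a$labels), levels(b$labels))) {
      ia <- which(a$labels == cl); ib <- which(b$labels == cl)
      m <- min(length(ia), length(ib))
      rows_a <- c(rows_a, sample(ia, m)); rows_b <- c(rows_b, sample(ib, m))
      labs <- c(labs, rep(cl, m))
    }
    vals <- cbind(a$values[rows_a, , drop = FALSE],
                  b$values[rows_b, , drop = FALSE])
    colnames(vals) <- c(paste0(names(tables)[1L], "_", colnames(a$values)),
                        paste0(names(tables)[2L], "_", colnames(b$values)))
    feature_table(vals, labs)
  })
}

#' Run the full CAD pipeline on an image manifest
#'
#' Orchestrates the end-to-end system: segmentation, hybrid feature
#' extraction (deep, PCA texture, shape) per modality, optional two-modality
#' fusion by seeded within-class pairing, genetic-algorithm and
#' mutual-information feature selection with concatenation fusion, random
#' undersampling, a stratified train/test split, classifier training and
#' imbalance-aware evaluation. All intermediate artifacts are written under
#' `out_dir`.
#'
#' @param manifest_path CSV with columns `path`, `mask_path`, `modality`,
#'   `label` (benign/malignant).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (default: a fresh temporary directory).
#' @return A list with `report` (the test-set `evaluation_report`),
#'   `selected` (fused feature table), `ga`, `mi` selection masks, `split`,
#'   `feature_width`, `out_dir`.
#' @export
run_pipeline <- function(manifest_path, config = pipeline_config(),
                         out_dir = tempfile("fusioncad_run_")) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "modality", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns path, modality, label")
  if (!all(manifest$label %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  logf("samples: %d; modalities: %s", nrow(manifest),
       paste(unique(manifest$modality), collapse = ","))

  mods <- unique(manifest$modality)
  tabs <- lapply(mods, function(mod) {
    sub <- manifest[manifest$modality == mod, , drop = FALSE]
    ft <- build_feature_table(sub, config)
    logf("modality %s: %d samples x %d features", mod,
         nrow(ft$table$values), ncol(ft$table$values))
    ft$table
  })
  names(tabs) <- mods
  table <- if (length(tabs) == 1L) tabs[[1L]] else
    pair_modalities(tabs, config$pair_seed)
  feature_width <- ncol(table$values)
  utils::write.csv(data.frame(label = table$labels, table$values,
                              check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  ga_mask <- ga_select(table, config$ga)
  mi_mask <- select_top_k(mi_scores(table, config$mi_k), config$mi_top_k)
  for (m in list(ga_mask, mi_mask)) {
    jsonlite::write_json(
      list(method = m$method,
           kept_columns = table$column_names[m$keep],
           scores = as.numeric(m$scores)),
      file.path(out_dir, sprintf("selection_%s.json", tolower(m$method))),
      auto_unbox = TRUE, digits = NA)
  }
  fused <- fuse_selections(table, ga_mask, mi_mask)
  logf("selection: GA kept %d, MI kept %d, fused width %d",
       sum(ga_mask$keep), sum(mi_mask$keep), ncol(fused$values))

  balanced <- random_undersample(fused, config$rus_seed)
  split <- stratified_split(balanced, config$split_fraction, config$split_seed)
  logf("balanced: %d samples; split: %d train / %d test",
       nrow(balanced$values), nrow(split$train$values),
       nrow(split$test$values))

  adapter <- classifier_adapter(config$classifier, config$classifier_params,
                                config$classifier_seed)
  fit <- adapter$fit(split$train)
  pred <- fit$predict(split$test$values)
  report <- evaluate_predictions(split$test$labels, pred)
  utils::write.csv(data.frame(truth = split$test$labels, prediction = pred),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(confusion = report$confusion,
         per_class = as.data.frame(report$per_class),
         macro = as.list(report$per_class["macro", ]),
         classifier = config$classifier,
         feature_width = feature_width,
         fused_width = ncol(fused$values),
         seeds = list(ga = config$ga$seed, rus = config$rus_seed,
                      split = config$split_seed,
                      classifier = config$classifier_seed,
                      deep = config$deep_seed, pair = config$pair_seed)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  logf("test accuracy: %.4f", report$accuracy)
  list(report = report, selected = fused, ga = ga_mask, mi = mi_mask,
       split = split, feature_width = feature_width, out_dir = out_dir)
}
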