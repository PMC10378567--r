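#' Specification of one synthetic lesion image
#'
#' Describes a single simulated lesion patch: an elliptical mass whose
#' boundary is radially perturbed by a sinusoid to mimic spiculation, drawn
#' on a modality-specific background. Benign lesions are smooth
#' (`spiculation_count = 0`); malignant lesions carry at least 5 spicules.
#'
#' @param modality `"US"` (speckle-corrupted ultrasound patch) or `"MG"`
#'   (low-contrast mammography patch with bright label artifacts).
#' @param class_label `"benign"` or `"malignant"`.
#' @param image_size Square image side in pixels.
#' @param center Lesion center (row, col); defaults to the image center.
#' @param base_radius Mean lesion radius in pixels; must satisfy
#'   `base_radius * (1 + spiculation_depth) < image_size / 2 - 26` so the
#'   padded bounding box fits inside the image.
#' @param spiculation_count Number of radial spicules (0 for benign, >= 5
#'   for malignant).
#' @param spiculation_depth Spicule amplitude as a fraction of the radius,
#'   in \[0, 1).
#' @param contrast Lesion-over-background intensity offset in \[0, 255\].
#' @param noise_level Modality corruption scale: speckle amplitude for US
#'   (image * (1 + u), u uniform on (-a, a)); gradient + Gaussian noise
#'   scale for MG.
#' @param seed Integer seed; identical specs give bit-identical images.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(modality = c("MG", "US"),
                        class_label = c("benign", "malignant"),
                        image_size = 128L, center = NULL,
                        base_radius = 24L,
                        spiculation_count = if (match.arg(class_label) == "benign") 0L else 8L,
                        spiculation_depth = if (spiculation_count > 0L) 0.3 else 0,
                        contrast = 90L, noise_level = 0.15, seed = 1L) {
  modality <- match.arg(modality)
  class_label <- match.arg(class_label)
  if (is.null(center)) center <- c(image_size / 2, image_size / 2)
  if (class_label == "benign" && spiculation_count != 0L)
    stop("benign lesions must have spiculation_count = 0")
  if (class_label == "malignant" && spiculation_count < 5L)
    stop("malignant lesions must have spiculation_count >= 5")
  if (spiculation_depth < 0 || spiculation_depth >= 1)
    stop("spiculation_depth must be in [0, 1)")
  if (base_radius >= image_size / 2 - 26)
    stop("base_radius too large for the padded bounding box to fit")
  structure(list(modality = modality, class_label = class_label,
                 image_size = as.integer(image_size), center = center,
                 base_radius = base_radius,
                 spiculation_count = as.integer(spiculation_count),
                 spiculation_depth = spiculation_depth,
                 contrast = contrast, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

# Rasterize the lesion: pixel inside iff its polar radius about the center
# is below the (ellipse x sinusoid) boundary radius at that angle.
rasterize_lesion <- function(spec, phase, axis_ratio, angle) {
  s <- spec$image_size
  r0 <- spec$center[1L]; c0 <- spec$center[2L]
  rr <- matrix(seq_len(s), s, s) - r0
  cc <- matrix(seq_len(s), s, s, byrow = TRUE) - c0
  # rotate into the ellipse frame
  u <- cos(angle) * cc + sin(angle) * rr
  v <- -sin(angle) * cc + cos(angle) * rr
  theta <- atan2(rr, cc)
  rad_ell <- spec$base_radius * axis_ratio /
    sqrt((axis_ratio * cos(theta - angle))^2 + sin(theta - angle)^2)
  bound <- rad_ell * (1 + spec$spiculation_depth *
                        sin(spec$spiculation_count * theta + phase))
  d <- sqrt(rr^2 + cc^2)
  (d <= bound) + 0L
}

#' Generate one synthetic lesion image and its ground-truth mask
#'
#' Rasterizes the lesion exactly, adds it to a modality-specific background
#' (`image = background + contrast * mask`), then applies the modality
#' corruption: multiplicative uniform speckle for US; a smooth additive
#' low-frequency gradient, Gaussian noise, and 1-3 bright rectangular
#' "label" artifacts away from the lesion for MG. With `noise_level = 0`
#' the uncorrupted ideal (background + contrast, no artifacts) is returned.
#' Output is deterministic in the spec (including its seed).
#'
#' @param spec A [lesion_spec()].
#' @return A list with `image` (`gray_image`) and `mask` (`lesion_mask`).
#' @export
make_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  s <- spec$image_size
  with_seed(spec$seed, {
    phase <- runif(1, 0, 2 * pi)
    axis_ratio <- runif(1, 0.75, 0.95)   # mild ellipticity for both classes
    angle <- runif(1, 0, pi)
    mask <- rasterize_lesion(spec, phase, axis_ratio, angle)
    idx <- which(mask == 1L)
    r <- (idx - 1L) %% s + 1L; c <- (idx - 1L) %/% s + 1L
    if (length(idx) == 0L) stop("degenerate spec: empty lesion")
    if (min(r) <= 1L || max(r) >= s || min(c) <= 1L || max(c) >= s)
      stop("lesion touches the image border")
    if (spec$modality == "US") {
      img <- 40 + spec$contrast * mask
      if (spec$noise_level > 0)
        img <- img * (1 + matrix(runif(s * s, -spec$noise_level,
                                       spec$noise_level), s, s))
    } else {
      img <- 50 + spec$contrast * mask
      if (spec$noise_level > 0) {
        gr <- matrix(seq(0, 1, length.out = s), s, s)
        gc <- matrix(seq(0, 1, length.out = s), s, s, byrow = TRUE)
        wr <- runif(2, -1, 1)
        img <- img + spec$noise_level * 3 * (wr[1L] * gr + wr[2L] * gc + 1) / 2
        img <- img + matrix(rnorm(s * s, sd = spec$noise_level), s, s)
        img <- add_mg_artifacts(img, mask, spec)
      }
    }
    img <- round(img)
    img[img < 0] <- 0; img[img > 255] <- 255
    list(image = gray_image(img), mask = lesion_mask(mask))
  })
}

# 1-3 bright axis-aligned rectangles placed outside the padded lesion box,
# mimicking view labels / markers burnt into mammography films.
add_mg_artifacts <- function(img, mask, spec) {
  s <- spec$image_size
  idx <- which(mask == 1L)
  r <- (idx - 1L) %% s + 1L; c <- (idx - 1L) %/% s + 1L
  pad <- 6L
  box <- c(min(r) - pad, max(r) + pad, min(c) - pad, max(c) + pad)
  n_art <- sample.int(3L, 1L)
  for (i in seq_len(n_art)) {
    for (try in 1:20) {
      h <- sample(6:14, 1L); w <- sample(6:14, 1L)
      rr <- sample.int(s - h, 1L); cc <- sample.int(s - w, 1L)
      overlaps <- !(rr + h < box[1L] || rr > box[2L] ||
                    cc + w < box[3L] || cc > box[4L])
      if (!overlaps) {
        img[rr:(rr + h), cc:(cc + w)] <- 240
        break
      }
    }
  }
  img
}

#' Write a seeded synthetic lesion dataset to disk
#'
#' Generates `n_per_class` benign and malignant lesions for each requested
#' modality, with randomized centers, radii, spiculation and phases, and
#' writes PNG images, PNG ground-truth masks and a CSV manifest with
#' columns `path`, `mask_path`, `modality`, `label`.
#'
#' @param dir Output directory (created if needed).
#' @param n_per_class Images per class per modality.
#' @param modalities Character vector from c("MG", "US").
#' @param image_size Square image side in pixels.
#' @param contrast,noise_level Passed to [lesion_spec()].
#' @param seed Master seed; per-image seeds are derived from it.
#' @return The manifest path, invisibly; the manifest data frame as the
#'   `manifest` attribute.
#' @export
write_lesion_dataset <- function(dir, n_per_class = 60L, modalities = "MG",
                                 image_size = 128L, contrast = 90L,
                                 noise_level = 0.15, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  with_seed(seed, {
    for (mod in modalities) {
      nl <- if (mod == "US") noise_level else max(1, noise_level * 40)
      for (lab in c("benign", "malignant")) {
        for (i in seq_len(n_per_class)) {
          sp <- lesion_spec(
            modality = mod, class_label = lab, image_size = image_size,
            center = image_size / 2 + round(runif(2, -8, 8)),
            base_radius = round(runif(1, 17, image_size / 2 - 28)),
            spiculation_count = if (lab == "benign") 0L else sample(5:12, 1L),
            spiculation_depth = if (lab == "benign") 0 else runif(1, 0.25, 0.4),
            contrast = contrast, noise_level = nl,
            seed = sample.int(.Machine$integer.max, 1L))
          out <- make_lesion_image(sp)
          base <- sprintf("%s_%s_%03d", tolower(mod), lab, i)
          ip <- file.path(dir, paste0(base, ".png"))
          mp <- file.path(dir, paste0(base, "_mask.png"))
          write_gray_png(out$image, ip)
          write_mask_png(out$mask, mp)
          rows[[length(rows) + 1L]] <-
            data.frame(path = ip, mask_path = mp, modality = mod,
                       label = lab, stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  attr(mpath, "manifest") <- manifest
  invisible(mpath)
}

#' Specification of a planted synthetic feature table
#'
#' @param n_per_class Samples per class.
#' @param n_features Total feature columns.
#' @param informative_indices 1-based indices of columns whose class means
#'   are separated.
#' @param effect_size Separation between class means in noise-SD units.
#' @param seed Integer seed.
#' @export
planted_spec <- function(n_per_class, n_features, informative_indices,
                         effect_size = 3, seed = 1L) {
  if (length(informative_indices) > n_features ||
      any(informative_indices < 1L) || any(informative_indices > n_features))
    stop("informative_indices must lie within 1..n_features")
  if (effect_size < 0) stop("effect_size must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 informative_indices = as.integer(informative_indices),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a feature table with a planted informative subset
#'
#' Informative columns are unit-variance Gaussians whose class means differ
#' by `effect_size`; all other columns are standard Gaussians identically
#' distributed across classes. Labels are balanced, `n_per_class` each.
#'
#' @param spec A [planted_spec()].
#' @return A [feature_table()].
#' @export
make_planted_feature_table <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  n <- 2L * spec$n_per_class
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(n * spec$n_features), n, spec$n_features)
    labels <- factor(rep(c("benign", "malignant"), each = spec$n_per_class),
                     levels = c("benign", "malignant"))
    shift <- ifelse(labels == "malignant", spec$effect_size / 2,
                    -spec$effect_size / 2)
    for (j in spec$informative_indices) x[, j] <- x[, j] + shift
    colnames(x) <- paste0("f", seq_len(spec$n_features))
    feature_table(x, labels)
  })
}
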