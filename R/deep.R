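#' Deep feature extractor contract
#'
#' A deep extractor is any object with a `name`, an `output_dim`, and an
#' `extract(img)` function returning a fixed-length numeric vector,
#' deterministically for a given image. The pipeline depends only on this
#' contract, so the bundled deterministic stub and any adapter to a
#' pretrained convolutional network are interchangeable.
#'
#' The default stub emulates the global-average-pool feature vector of a
#' DenseNet-201 backbone (width 1920): it resizes the image to a fixed
#' 32 x 32 grid, flattens it, projects it through a fixed random linear map
#' drawn once from `seed`, and squashes the result with tanh. It requires
#' no downloads and is reproducible across sessions.
#'
#' @param name `"stub"` or `"densenet201"`.
#' @param dim Output feature count (default 1920).
#' @param seed Seed fixing the stub's projection map.
#' @return A `deep_extractor` object (list with `name`, `output_dim`,
#'   `extract`).
#' @export
deep_extractor <- function(name = c("stub", "densenet201"), dim = 1920L,
                           seed = 42L) {
  name <- match.arg(name)
  if (dim < 1L) stop("`dim` must be >= 1")
  if (name == "densenet201") {
    extract <- function(img) {
      stop("no pretrained DenseNet-201 runtime is available; use ",
           "deep_extractor(\"stub\") for a deterministic drop-in extractor")
    }
    return(structure(list(name = name, output_dim = 1920L, extract = extract),
                     class = "deep_extractor"))
  }
  grid <- 32L
  proj <- with_seed(seed, matrix(stats::rnorm(grid * grid * dim,
                                              sd = 1 / sqrt(grid * grid)),
                                 grid * grid, dim))
  extract <- function(img) {
    v <- as.vector(resize_bilinear(img, grid, grid)) / 255
    as.vector(tanh(crossprod(proj, v)))
  }
  structure(list(name = name, output_dim = as.integer(dim), extract = extract),
            class = "deep_extractor")
}

#' Extract deep features from one image with the deterministic stub
#'
#' Convenience wrapper constructing a stub [deep_extractor()] and applying
#' it once.
#'
#' @param img ROI image.
#' @param dim Output length.
#' @param seed Projection-map seed.
#' @return Numeric vector of length `dim`.
#' @export
stub_extract <- function(img, dim = 1920L, seed = 42L) {
  deep_extractor("stub", dim = dim, seed = seed)$extract(img)
}
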