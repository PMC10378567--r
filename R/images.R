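#' Grayscale image container
#'
#' Images are plain integer matrices in row/column orientation with
#' intensities in \[0, 255\]. `gray_image()` validates a matrix and attaches
#' the `gray_image` class; all image operations in the package accept either
#' a `gray_image` or a bare matrix.
#'
#' @param pixels Numeric matrix; values are rounded and must lie in
#'   \[0, 255\] after rounding.
#' @return An integer matrix of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("intensities must be in [0, 255]")
  storage.mode(px) <- "integer"
  structure(px, class = c("gray_image", class(px)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

as_pixel_matrix <- function(img) {
  m <- unclass(img)
  if (!is.matrix(m)) stop("expected a matrix image")
  m
}

#' Binary lesion mask
#'
#' @param pixels Matrix of 0/1 (or logical) values.
#' @return Integer 0/1 matrix of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  px <- pixels + 0L
  if (!all(px %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  storage.mode(px) <- "integer"
  structure(px, class = c("lesion_mask", class(px)))
}

#' Read / write 8-bit grayscale PNG images
#'
#' Thin wrappers over the png package keeping the package's row/column
#' integer-intensity convention.
#'
#' @param path File path.
#' @rdname png_io
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]   # collapse grayscale-as-RGB
  gray_image(a * 255)
}

#' @param img A `gray_image` or matrix in \[0, 255\].
#' @rdname png_io
#' @export
write_gray_png <- function(img, path) {
  m <- as_pixel_matrix(img)
  png::writePNG(m / 255, path)
  invisible(path)
}

#' @param mask A binary mask.
#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_pixel_matrix(mask) + 0, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  lesion_mask((a > 0.5) + 0L)
}

#' Resize a grayscale image by bilinear interpolation
#'
#' @param img Image matrix in \[0, 255\].
#' @param nrow_out,ncol_out Output dimensions in pixels.
#' @return Numeric matrix of the requested size (not rounded, so descriptor
#'   inputs keep sub-integer precision).
#' @export
resize_bilinear <- function(img, nrow_out, ncol_out) {
  m <- as_pixel_matrix(img)
  out <- EBImage::resize(EBImage::Image(m / 255), w = nrow_out, h = ncol_out,
                         filter = "bilinear")
  r <- EBImage::imageData(out) * 255
  r[r < 0] <- 0; r[r > 255] <- 255
  r
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls never disturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
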