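#' Histogram equalization
#'
#' Spreads the intensity histogram over the full 8-bit range using the
#' cumulative distribution H(v) of the input intensities: each level v is
#' remapped to floor(255 * H(v) / N). The mapping is monotone non-decreasing,
#' so intensity ordering is preserved.
#'
#' @param img A `gray_image` or integer matrix in \[0, 255\].
#' @return A `gray_image` of the same size.
#' @export
equalize_histogram <- function(img) {
  m <- as_pixel_matrix(img)
  h <- tabulate(as.vector(m) + 1L, nbins = 256L)
  cdf <- cumsum(h)
  map <- floor(255 * cdf / length(m))
  gray_image(matrix(map[m + 1L], nrow(m), ncol(m)))
}

#' Median filter with edge replication
#'
#' Each output pixel is the exact median of its `window` x `window`
#' neighborhood; the image border is handled by edge replication.
#'
#' @param img Image matrix.
#' @param window Odd window side length, >= 3.
#' @return Filtered `gray_image`.
#' @export
median_filter <- function(img, window = 3L) {
  if (length(window) != 1L || window %% 2L == 0L || window < 3L)
    stop("`window` must be an odd integer >= 3")
  m <- as_pixel_matrix(img)
  nr <- nrow(m); nc <- ncol(m)
  half <- (window - 1L) / 2L
  # replicate-pad, then gather all window offsets into one wide matrix
  ri <- pmin(pmax(seq_len(nr + 2L * half) - half, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * half) - half, 1L), nc)
  pad <- m[ri, ci, drop = FALSE]
  k <- window * window
  neigh <- matrix(0L, nr * nc, k)
  idx <- 1L
  for (dc in 0:(window - 1L)) {
    for (dr in 0:(window - 1L)) {
      neigh[, idx] <- as.vector(pad[dr + seq_len(nr), dc + seq_len(nc)])
      idx <- idx + 1L
    }
  }
  # row-wise medians without per-row calls: sort all rows at once
  srt <- matrix(neigh[order(row(neigh), neigh)], nrow = nr * nc, byrow = TRUE)
  med <- srt[, (k + 1L) / 2L]
  gray_image(matrix(med, nr, nc))
}

#' Otsu threshold selection
#'
#' Exhaustive scan of all 8-bit thresholds maximizing the between-class
#' variance of the two resulting intensity groups.
#'
#' @param img Image matrix.
#' @return Integer threshold in \[0, 254\].
#' @export
otsu_threshold <- function(img) {
  m <- as_pixel_matrix(img)
  h <- tabulate(as.vector(m) + 1L, nbins = 256L)
  p <- h / sum(h)
  lv <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lv)
  mu_t <- mu[256]
  w1 <- 1 - w0
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  which.max(bcv[1:255]) - 1L   # threshold t means "> t is foreground"
}

#' Binarize an image at a fixed or automatic threshold
#'
#' Pixels strictly above the threshold become 1. `thr = "auto"` selects the
#' threshold by Otsu's between-class-variance criterion.
#'
#' @param img Image matrix.
#' @param thr Intensity threshold in \[0, 255\], or `"auto"`.
#' @return A `lesion_mask`.
#' @export
threshold_binarize <- function(img, thr = "auto") {
  m <- as_pixel_matrix(img)
  if (identical(thr, "auto")) thr <- otsu_threshold(m)
  if (!is.numeric(thr) || thr < 0 || thr > 255)
    stop("`thr` must be \"auto\" or an intensity in [0, 255]")
  lesion_mask((m > thr) + 0L)
}

# 8-connected component labelling by breadth-first frontier expansion.
label_components <- function(mask) {
  m <- as_pixel_matrix(mask)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(m == 1L)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                     c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
        rr <- r + d[1L]; cc <- c + d[2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        id <- (cc[ok] - 1L) * nr + rr[ok]
        id <- id[m[id] == 1L & lab[id] == 0L]
        if (length(id)) {
          lab[id] <- cur
          nxt <- c(nxt, id)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Suzuki-Abe border following of one component's outer border, clockwise,
# 8-connectivity. `start` is the component's topmost-leftmost pixel (row, col)
# whose scan-order predecessor in its row is background.
follow_border <- function(m, start) {
  nr <- nrow(m); nc <- ncol(m)
  # clockwise 8-neighborhood beginning at "left" (row, col-1)
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && m[r, c] != 0L
  i <- start[1L]; j <- start[2L]
  # step 3.1: first foreground neighbor clockwise from (i, j-1)
  k0 <- NA_integer_
  for (k in 1:8) {
    r <- i + nb[k, 1L]; c <- j + nb[k, 2L]
    if (fg(r, c)) { k0 <- k; break }
  }
  if (is.na(k0)) return(matrix(c(i, j), 1L, 2L))  # isolated pixel
  i1 <- i + nb[k0, 1L]; j1 <- j + nb[k0, 2L]
  pts <- list(c(i, j))
  i2 <- i1; j2 <- j1   # previously examined pixel
  i3 <- i; j3 <- j     # current border pixel
  repeat {
    # step 3.3: search counterclockwise from the element after (i2, j2)
    dk <- which(nb[, 1L] == i2 - i3 & nb[, 2L] == j2 - j3)
    found <- FALSE
    for (s in 1:8) {
      k <- ((dk - 1L - s) %% 8L) + 1L   # counterclockwise order
      r <- i3 + nb[k, 1L]; c <- j3 + nb[k, 2L]
      if (fg(r, c)) { i4 <- r; j4 <- c; found <- TRUE; break }
    }
    if (!found) break
    # step 3.5: termination when back at the start heading to the first pixel
    if (i4 == start[1L] && j4 == start[2L] && i3 == i1 && j3 == j1) break
    pts[[length(pts) + 1L]] <- c(i4, j4)
    i2 <- i3; j2 <- j3
    i3 <- i4; j3 <- j4
  }
  do.call(rbind, pts)
}

#' Trace outer contours of all foreground components
#'
#' Suzuki-Abe border following with 8-connectivity: returns, for every
#' connected foreground component in raster-scan order, the ordered closed
#' sequence of its outer border pixels.
#'
#' @param mask A binary `lesion_mask` or 0/1 matrix.
#' @return A list of contours; each contour is a list with `points`
#'   (n x 2 matrix of (row, col), 1-based) and `closed = TRUE`.
#' @export
trace_contours <- function(mask) {
  m <- as_pixel_matrix(mask)
  lab <- label_components(m)
  n <- max(lab)
  if (n == 0L) return(list())
  out <- vector("list", n)
  for (comp in seq_len(n)) {
    cm <- (lab == comp) + 0L
    idx <- which(cm == 1L)
    # topmost-leftmost in raster (row-major) order
    r <- (idx - 1L) %% nrow(m) + 1L
    c <- (idx - 1L) %/% nrow(m) + 1L
    o <- order(r, c)[1L]
    pts <- follow_border(cm, c(r[o], c[o]))
    out[[comp]] <- list(points = pts, closed = TRUE)
  }
  out
}

# Fill holes: background not 4-connected to the image border becomes
# foreground.
fill_mask_holes <- function(mask) {
  m <- as_pixel_matrix(mask)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m)))
  lesion_mask((filled != 0) + 0L)
}

#' Pick the largest lesion among traced contours
#'
#' Fills each contour's component (holes included) and returns the contour
#' whose filled region has the most pixels, together with that region as a
#' mask. Ties go to the component first reached in raster-scan order.
#'
#' @param contours List of contours from [trace_contours()].
#' @param mask The binary mask the contours were traced from.
#' @return A list with `contour` and `mask`.
#' @export
largest_lesion <- function(contours, mask) {
  if (length(contours) == 0L) stop("no lesion found")
  m <- as_pixel_matrix(mask)
  lab <- label_components(m)
  areas <- integer(length(contours))
  fills <- vector("list", length(contours))
  for (i in seq_along(contours)) {
    p1 <- contours[[i]]$points[1L, ]
    comp <- lab[p1[1L], p1[2L]]
    fm <- fill_mask_holes((lab == comp) + 0L)
    fills[[i]] <- fm
    areas[i] <- sum(fm)
  }
  best <- which.max(areas)   # first maximum = raster-scan tie-break
  list(contour = contours[[best]], mask = fills[[best]])
}

#' Padded bounding box of a contour
#'
#' Minimal enclosing rectangle of the contour points, expanded by
#' `tolerance` pixels on all four sides and clipped to the image bounds.
#'
#' @param contour A contour (list with `points`), or an n x 2 point matrix.
#' @param tolerance Non-negative padding in pixels (default 25).
#' @param image_shape c(nrow, ncol) of the image the box must stay inside.
#' @return A list with inclusive 1-based `row_min`, `row_max`, `col_min`,
#'   `col_max`.
#' @export
bounding_box <- function(contour, tolerance = 25L, image_shape) {
  pts <- if (is.list(contour)) contour$points else contour
  if (is.null(pts) || nrow(pts) == 0L) stop("empty contour")
  if (tolerance < 0) stop("`tolerance` must be >= 0")
  list(row_min = max(1L, min(pts[, 1L]) - tolerance),
       row_max = min(image_shape[1L], max(pts[, 1L]) + tolerance),
       col_min = max(1L, min(pts[, 2L]) - tolerance),
       col_max = min(image_shape[2L], max(pts[, 2L]) + tolerance))
}

crop_box <- function(img, box) {
  as_pixel_matrix(img)[box$row_min:box$row_max, box$col_min:box$col_max,
                       drop = FALSE]
}

#' Segmentation configuration
#'
#' @param threshold `"auto"` (Otsu) or a fixed intensity in \[0, 255\].
#' @param median_pre Window of the pre-threshold median filter (3 or 5).
#' @param median_post Window of the post-threshold median filter (default 9).
#' @param tolerance Bounding-box padding in pixels (default 25).
#' @export
segment_config <- function(threshold = "auto", median_pre = 3L,
                           median_post = 9L, tolerance = 25L) {
  list(threshold = threshold, median_pre = as.integer(median_pre),
       median_post = as.integer(median_post), tolerance = as.integer(tolerance))
}

#' Segment a lesion and extract its region of interest
#'
#' The full preprocessing chain: histogram equalization, small median filter,
#' binarization, 9x9 median filter, hole filling, Suzuki-Abe contour tracing,
#' largest-component selection, and a 25-pixel-padded bounding-box crop of
#' the original image.
#'
#' @param img Input `gray_image`.
#' @param config A [segment_config()].
#' @return A list with `mask` (full-size lesion mask), `roi` (cropped
#'   `gray_image`), `roi_mask` (mask cropped to the same box), `contour`,
#'   and `box`.
#' @export
segment_lesion <- function(img, config = segment_config()) {
  m <- as_pixel_matrix(img)
  eq <- equalize_histogram(m)
  sm <- median_filter(eq, config$median_pre)
  bw <- threshold_binarize(sm, config$threshold)
  if (all(bw == 1L) || all(bw == 0L))
    stop("no lesion found")   # featureless image: nothing separates from background
  bw <- median_filter(bw * 255L, config$median_post)
  bw <- lesion_mask((as_pixel_matrix(bw) > 127) + 0L)
  bw <- fill_mask_holes(bw)
  contours <- trace_contours(bw)
  if (length(contours) == 0L) stop("no lesion found")
  best <- largest_lesion(contours, bw)
  box <- bounding_box(best$contour, config$tolerance, dim(m))
  list(mask = best$mask,
       roi = gray_image(crop_box(m, box)),
       roi_mask = lesion_mask(crop_box(best$mask, box)),
       contour = best$contour,
       box = box)
}
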