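#' BI-RADS-motivated shape features of a lesion mask
#'
#' Computes the four morphological descriptors used to separate smooth
#' (typically benign) from spiculated (typically malignant) lesions:
#'
#' * **area** — foreground pixel count;
#' * **perimeter** — Euclidean chain length of the closed traced boundary
#'   (1 per axis-aligned step, sqrt(2) per diagonal step);
#' * **eccentricity** — a central-moment expression
#'   ((mu02 - mu20)^2 + 4 mu11) / area computed with raw (unnormalized)
#'   central moments (`method = "moments"`, the default); or the standard
#'   ellipse-axis eccentricity sqrt(1 - (minor/major)^2) from the second
#'   moments (`method = "ellipse"`);
#' * **circularity** — 4 pi area / perimeter^2, close to 1 for disks and
#'   decreasing with boundary irregularity.
#'
#' @param mask Binary lesion mask with at least one foreground pixel.
#' @param contour Traced boundary of the mask (from [trace_contours()]);
#'   recomputed when omitted.
#' @param method Eccentricity convention, `"moments"` or `"ellipse"`.
#' @return A list with `area`, `perimeter`, `eccentricity`, `circularity`.
#' @export
shape_features <- function(mask, contour = NULL, method = c("moments", "ellipse")) {
  method <- match.arg(method)
  m <- as_pixel_matrix(mask)
  area <- sum(m != 0)
  if (area == 0L) stop("empty mask")
  if (is.null(contour)) {
    cs <- trace_contours(m)
    best <- largest_lesion(cs, m)
    contour <- best$contour
  }
  pts <- if (is.list(contour)) contour$points else contour
  # closed Euclidean chain length
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  per <- sum(sqrt(rowSums((nxt - pts)^2)))
  if (per == 0) per <- 1   # single-pixel lesion: unit perimeter
  idx <- which(m != 0)
  r <- (idx - 1L) %% nrow(m) + 1L
  c <- (idx - 1L) %/% nrow(m) + 1L
  rb <- mean(r); cb <- mean(c)
  mu20 <- sum((c - cb)^2)   # x = column axis
  mu02 <- sum((r - rb)^2)
  mu11 <- sum((c - cb) * (r - rb))
  ecc <- if (method == "moments") {
    ((mu02 - mu20)^2 + 4 * mu11) / area
  } else {
    # ellipse-axis eccentricity from normalized second moments
    m20 <- mu20 / area; m02 <- mu02 / area; m11 <- mu11 / area
    common <- sqrt((m20 - m02)^2 + 4 * m11^2)
    l1 <- (m20 + m02 + common) / 2
    l2 <- (m20 + m02 - common) / 2
    if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
  }
  list(area = area,
       perimeter = per,
       eccentricity = ecc,
       circularity = 4 * pi * area / per^2)
}
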