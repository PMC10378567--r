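#' Local binary pattern code image
#'
#' Codes every interior pixel by comparing its p circular neighbors at
#' radius r against the center, clockwise from the top-right neighbor, and
#' reading the comparison bits as a base-2 number (bit i has weight 2^i).
#' The default convention sets a bit when the neighbor is greater than or
#' equal to the center; `literal_sign = TRUE` instead sets a bit when
#' neighbor - center is strictly negative.
#'
#' @param img Image matrix in \[0, 255\].
#' @param p Number of neighbors (8 supported).
#' @param r Radius in pixels (1 supported).
#' @param literal_sign Use the strictly-negative-difference convention.
#' @return Integer matrix of codes in \[0, 2^p - 1\] of size
#'   (nrow - 2r) x (ncol - 2r); border pixels are excluded.
#' @export
lbp_code_image <- function(img, p = 8L, r = 1L, literal_sign = FALSE) {
  if (p != 8L || r != 1L) stop("only p = 8, r = 1 is supported")
  m <- as_pixel_matrix(img)
  if (nrow(m) < 2L * r + 1L || ncol(m) < 2L * r + 1L)
    stop("image smaller than the LBP window")
  nr <- nrow(m); nc <- ncol(m)
  ctr <- m[2:(nr - 1L), 2:(nc - 1L)]
  # clockwise from top-right: (row, col) offsets
  off <- rbind(c(-1L, 1L), c(0L, 1L), c(1L, 1L), c(1L, 0L),
               c(1L, -1L), c(0L, -1L), c(-1L, -1L), c(-1L, 0L))
  codes <- matrix(0L, nr - 2L, nc - 2L)
  for (i in seq_len(8L)) {
    nb <- m[2:(nr - 1L) + off[i, 1L], 2:(nc - 1L) + off[i, 2L]]
    bit <- if (literal_sign) (nb - ctr) < 0 else nb >= ctr
    codes <- codes + bit * 2L^(i - 1L)
  }
  structure(codes, p = p, r = r)
}

#' Histogram of LBP codes
#'
#' @param codes Code matrix from [lbp_code_image()].
#' @return Integer vector of 2^p bin counts (bin k counts code k, k from 0).
#' @export
lbp_histogram <- function(codes) {
  p <- attr(codes, "p"); if (is.null(p)) p <- 8L
  tabulate(as.vector(codes) + 1L, nbins = 2L^p)
}

#' Image gradients for HOG
#'
#' Central differences Gx(r, c) = I(r, c+1) - I(r, c-1) along columns and
#' Gy(r, c) = I(r+1, c) - I(r-1, c) along rows, with replicated edges;
#' magnitude sqrt(Gx^2 + Gy^2) and unsigned orientation
#' atan2(Gy, Gx) folded into \[0, 180) degrees.
#'
#' @param img Image matrix.
#' @return List with `magnitude` and `orientation` matrices.
#' @export
hog_gradients <- function(img) {
  m <- as_pixel_matrix(img)
  if (nrow(m) < 3L || ncol(m) < 3L) stop("image must be at least 3 x 3")
  nr <- nrow(m); nc <- ncol(m)
  cl <- pmax(seq_len(nc) - 1L, 1L); cr <- pmin(seq_len(nc) + 1L, nc)
  ru <- pmax(seq_len(nr) - 1L, 1L); rd <- pmin(seq_len(nr) + 1L, nr)
  gx <- m[, cr, drop = FALSE] - m[, cl, drop = FALSE]
  gy <- m[rd, , drop = FALSE] - m[ru, , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180           # unsigned orientation
  list(magnitude = mag, orientation = ang)
}

#' Cell orientation histograms for HOG
#'
#' Splits the gradient field into non-overlapping `cell` x `cell` cells and
#' accumulates magnitude-weighted orientation votes into `bins` bins of
#' width 180/bins degrees. Each pixel's vote is shared linearly between the
#' two bins whose centers straddle its orientation (circular wrap between
#' the last and first bin).
#'
#' @param field Gradient field from [hog_gradients()].
#' @param cell Cell side in pixels (default 8).
#' @param bins Number of orientation bins (default 9).
#' @return A 3-D array cells_rows x cells_cols x bins.
#' @export
hog_cell_histograms <- function(field, cell = 8L, bins = 9L) {
  mag <- field$magnitude; ang <- field$orientation
  nr <- nrow(mag); nc <- ncol(mag)
  if (nr %% cell != 0L || nc %% cell != 0L)
    stop("image dimensions must be multiples of the cell size")
  w <- 180 / bins
  # soft assignment: lower bin j has center w*(j + 1/2)
  jf <- floor(ang / w - 0.5)
  cj <- w * (jf + 0.5)
  wt_hi <- (ang - cj) / w          # weight for bin j + 1
  wt_lo <- 1 - wt_hi
  j_lo <- (as.integer(jf) %% bins)         # 0-based bins, circular
  j_hi <- ((as.integer(jf) + 1L) %% bins)
  cr <- (row(mag) - 1L) %/% cell
  cc <- (col(mag) - 1L) %/% cell
  ncr <- nr %/% cell; ncc <- nc %/% cell
  hist <- array(0, c(ncr, ncc, bins))
  id_lo <- cr + ncr * cc + ncr * ncc * j_lo + 1L
  id_hi <- cr + ncr * cc + ncr * ncc * j_hi + 1L
  acc_lo <- rowsum(as.vector(mag * wt_lo), as.vector(id_lo))
  acc_hi <- rowsum(as.vector(mag * wt_hi), as.vector(id_hi))
  hist[as.integer(rownames(acc_lo))] <- acc_lo
  hist[as.integer(rownames(acc_hi))] <-
    hist[as.integer(rownames(acc_hi))] + acc_hi
  hist
}

#' Block-normalized HOG descriptor
#'
#' Slides a 2x2-cell block over the cell grid with a one-cell (8-pixel)
#' stride, flattens each block's 4 x bins histogram values to a vector of
#' 36 and L2-normalizes it as v / sqrt(||v||^2 + eps), then concatenates
#' all blocks.
#'
#' @param cells Cell histogram array from [hog_cell_histograms()].
#' @param block Block side in cells (default 2).
#' @param epsilon Normalization constant (default 1e-5).
#' @return Numeric descriptor of length n_blocks * block^2 * bins.
#' @export
hog_descriptor <- function(cells, block = 2L, epsilon = 1e-5) {
  ncr <- dim(cells)[1L]; ncc <- dim(cells)[2L]; bins <- dim(cells)[3L]
  nbr <- ncr - block + 1L; nbc <- ncc - block + 1L
  if (nbr < 1L || nbc < 1L) stop("no full block fits the cell grid")
  out <- numeric(nbr * nbc * block * block * bins)
  len <- block * block * bins
  k <- 0L
  for (bc in seq_len(nbc)) {
    for (br in seq_len(nbr)) {
      v <- as.vector(cells[br:(br + block - 1L), bc:(bc + block - 1L), ])
      out[k + seq_len(len)] <- v / sqrt(sum(v^2) + epsilon)
      k <- k + len
    }
  }
  out
}

#' Texture feature vector (HOG + LBP)
#'
#' Resizes the ROI to a fixed square descriptor input (bilinear), computes
#' the block-normalized HOG descriptor and the 256-bin LBP histogram
#' (normalized to frequencies), and concatenates them. The vector length is
#' fixed for a fixed configuration.
#'
#' @param img ROI image matrix.
#' @param input_size Square descriptor input side (default 128, a multiple
#'   of the cell size).
#' @param cell,bins,block,epsilon HOG parameters.
#' @return Named numeric vector `hog_*` then `lbp_*`.
#' @export
texture_vector <- function(img, input_size = 128L, cell = 8L, bins = 9L,
                           block = 2L, epsilon = 1e-5) {
  rs <- resize_bilinear(img, input_size, input_size)
  g <- hog_gradients(rs)
  hog <- hog_descriptor(hog_cell_histograms(g, cell, bins), block, epsilon)
  codes <- lbp_code_image(round(rs))
  lbp <- lbp_histogram(codes)
  lbp <- lbp / sum(lbp)
  v <- c(hog, lbp)
  names(v) <- c(paste0("hog_", seq_along(hog) - 1L),
                paste0("lbp_", seq_along(lbp) - 1L))
  v
}

#' Fit a principal component analysis model
#'
#' Centers the data and eigendecomposes its covariance (computed via the
#' thin singular value decomposition of the centered matrix, which yields
#' the same eigenvectors and eigenvalues without forming the p x p
#' covariance). Components are sorted by explained variance, descending,
#' with a deterministic sign convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param x Numeric matrix, samples in rows.
#' @param n_components Number of components to retain; capped at
#'   min(n_samples - 1, n_features) with a warning when the cap binds.
#' @return An object of class `pca_model` with `mean`, `components`
#'   (features x n_components), `explained_variance`, `n_components`.
#' @export
pca_fit <- function(x, n_components = 199L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  cap <- min(n - 1L, p)
  if (n_components > cap) {
    warning(sprintf("n_components reduced from %d to %d (rank cap)",
                    n_components, cap))
    n_components <- cap
  }
  if (n_components < 1L) stop("need at least 2 samples and 1 feature")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0, nv = n_components)
  ev <- (sv$d^2) / (n - 1L)
  comp <- sv$v
  # sign convention: largest |loading| positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, components = comp,
                 explained_variance = ev[seq_len(n_components)],
                 total_variance = sum(ev),
                 n_components = n_components),
            class = "pca_model")
}

#' Project data onto a fitted PCA basis
#'
#' @param model A `pca_model` from [pca_fit()].
#' @param x Matrix with the same feature count the model was fitted on.
#' @return n x n_components matrix of scores.
#' @export
pca_transform <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop("feature count does not match the fitted model")
  sweep(x, 2L, model$mean) %*% model$components
}

#' Reconstruct data from PCA scores
#'
#' @param model A `pca_model`.
#' @param scores Score matrix from [pca_transform()].
#' @return Reconstruction in the original feature space.
#' @export
pca_inverse <- function(model, scores) {
  scores %*% t(model$components) + rep(model$mean, each = nrow(scores))
}
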