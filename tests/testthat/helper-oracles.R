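# Brute-force oracles kept deliberately independent of the package
# implementations: plain loops and flood fills, no shared helpers.

# 8-connected component labelling by repeated scanning (slow, simple).
oracle_label8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(m == 1)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            m[rr, cc] == 1 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack <- c(stack, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  lab
}

# Outer-boundary pixels of a single-component mask: foreground pixels
# 4-adjacent to background that is 4-connected to the image frame.
oracle_outer_boundary <- function(cm) {
  nr <- nrow(cm); nc <- ncol(cm)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- cm
  out <- matrix(FALSE, nr + 2L, nc + 2L)
  stack <- which(pad == 0 & (row(pad) %in% c(1L, nr + 2L) |
                             col(pad) %in% c(1L, nc + 2L)))
  out[stack] <- TRUE
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    r <- (p - 1L) %% (nr + 2L) + 1L; c <- (p - 1L) %/% (nr + 2L) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      if (rr >= 1 && rr <= nr + 2L && cc >= 1 && cc <= nc + 2L &&
          pad[rr, cc] == 0 && !out[rr, cc]) {
        out[rr, cc] <- TRUE
        stack <- c(stack, (cc - 1L) * (nr + 2L) + rr)
      }
    }
  }
  res <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (cm[r, c] != 1) next
    touches <- out[r, c + 1L] || out[r + 2L, c + 1L] ||
               out[r + 1L, c] || out[r + 1L, c + 2L]
    if (touches) res <- c(res, (c - 1L) * nr + r)
  }
  sort(res)
}

# All outer-boundary pixels of a mask, component by component.
oracle_boundary_pixels <- function(m) {
  lab <- oracle_label8(m)
  res <- integer(0)
  for (k in seq_len(max(lab, 0L)))
    res <- c(res, oracle_outer_boundary((lab == k) + 0L))
  sort(res)
}

contour_pixel_set <- function(contours, nr) {
  sort(unique(unlist(lapply(contours, function(ct)
    (ct$points[, 2L] - 1L) * nr + ct$points[, 1L]))))
}

# Naive per-pixel median filter with edge replication.
oracle_median <- function(m, window) {
  half <- (window - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- pmin(pmax((r - half):(r + half), 1L), nr)
    cs <- pmin(pmax((c - half):(c + half), 1L), nc)
    out[r, c] <- median(as.vector(m[rs, cs]))
  }
  out
}

# Naive LBP (p = 8, r = 1), clockwise from top-right, bit i weight 2^i.
oracle_lbp <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  off <- rbind(c(-1, 1), c(0, 1), c(1, 1), c(1, 0),
               c(1, -1), c(0, -1), c(-1, -1), c(-1, 0))
  out <- matrix(0L, nr - 2L, nc - 2L)
  for (r in 2:(nr - 1L)) for (c in 2:(nc - 1L)) {
    code <- 0L
    for (i in 1:8) {
      nb <- m[r + off[i, 1L], c + off[i, 2L]]
      if (nb >= m[r, c]) code <- code + 2L^(i - 1L)
    }
    out[r - 1L, c - 1L] <- code
  }
  out
}

# Naive central-difference gradients with replicated edges.
oracle_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx[r, c] <- m[r, min(c + 1L, nc)] - m[r, max(c - 1L, 1L)]
    gy[r, c] <- m[min(r + 1L, nr), c] - m[max(r - 1L, 1L), c]
  }
  list(gx = gx, gy = gy)
}

# A filled disk mask of the given radius centred in a square image.
disk_mask <- function(radius, size = 2L * radius + 11L) {
  ctr <- (size + 1) / 2
  m <- matrix(0L, size, size)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- 1L
  m
}
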