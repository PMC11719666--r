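# Low-level raster primitives shared by the texture and segmentation code.
# All filters use mirror padding (edge pixel included) so that constant
# images stay exactly constant under smoothing.

pad_reflect <- function(m, k) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (k >= nr || k >= nc) {
    rlang::abort("Padding exceeds image size; image too small for this window.")
  }
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a 1-D tap vector applied along rows (dim = 1,
# i.e. vertically) or columns (dim = 2), mirror padding. The kernel is used
# in correlation orientation; all kernels here are symmetric or
# antisymmetric so the distinction only flips signs of odd kernels, which
# the absolute-energy features ignore. Tap count must be odd.
conv1d <- function(m, taps, dim) {
  k <- (length(taps) - 1L) %/% 2L
  p <- pad_reflect(m, k)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (u in seq_along(taps)) {
    off <- u - 1L
    if (dim == 1L) {
      out <- out + taps[u] * p[(1 + off):(nr + off), (k + 1):(k + nc), drop = FALSE]
    } else {
      out <- out + taps[u] * p[(k + 1):(k + nr), (1 + off):(nc + off), drop = FALSE]
    }
  }
  out
}

# 2-D convolution with a separable kernel outer(v_row, v_col).
conv_sep <- function(m, v_row, v_col) {
  conv1d(conv1d(m, v_row, dim = 1L), v_col, dim = 2L)
}

# Moving-window sum over a (2k+1) x (2k+1) square, mirror padding,
# computed with summed-area tables.
box_sum <- function(m, k) {
  p <- pad_reflect(m, k)
  s <- apply(apply(p, 2, cumsum), 1, cumsum)
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  w <- 2L * k + 1L
  nr <- nrow(m)
  nc <- ncol(m)
  r1 <- 1:nr
  c1 <- 1:nc
  s[r1 + w, c1 + w, drop = FALSE] - s[r1, c1 + w, drop = FALSE] -
    s[r1 + w, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
}

box_mean <- function(m, k) {
  box_sum(m, k) / (2 * k + 1)^2
}

# Gaussian blur, separable, sigma in pixels; sigma <= 0 is the identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  taps <- exp(-x^2 / (2 * sigma^2))
  taps <- taps / sum(taps)
  conv_sep(m, taps, taps)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels whose pixels touch diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  mask <- as_binary_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(t(mask) * 1))
  lab <- t(lab)
  n <- max(lab)
  if (n <= 1) {
    return(lab)
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  a1 <- lab[-nr, -nc]
  b1 <- lab[-1, -1] # down-right diagonal pairs
  a2 <- lab[-1, -nc]
  b2 <- lab[-nr, -1] # up-right diagonal pairs
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(
    cbind(a1[keep1], b1[keep1]),
    cbind(a2[keep2], b2[keep2])
  ))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1])
      rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Keep the largest 8-connected component and fill its holes.
clean_mask <- function(mask) {
  lab <- label_components8(mask)
  if (max(lab) == 0) {
    rlang::abort("Mask has no foreground pixels.")
  }
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  keep <- lab == big
  filled <- EBImage::fillHull(t(keep) * 1)
  t(EBImage::imageData(filled)) > 0
}

# Binary erosion by a (2k+1) x (2k+1) square: keep pixels whose whole
# window lies inside the mask. Pixels closer than k to the border are
# dropped (the window must be fully interior).
erode_mask <- function(mask, k) {
  mask <- as_binary_mask(mask)
  full <- (2 * k + 1)^2
  inner <- box_sum(mask * 1, k) >= full - 1e-9
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (nr <= 2 * k || nc <= 2 * k) {
    return(matrix(FALSE, nr, nc))
  }
  border <- matrix(FALSE, nr, nc)
  border[(k + 1):(nr - k), (k + 1):(nc - k)] <- TRUE
  inner & border
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) {
    return(NA_real_)
  }
  sqrt(sum((x - mean(x))^2) / n)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
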