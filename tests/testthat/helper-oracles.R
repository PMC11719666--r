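# Independent oracles, all deliberately written as plain loops so they
# share no code with the package's vectorized implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook sRGB (D65, 2 deg) -> CIELAB for one pixel, scalar arithmetic.
oracle_rgb2lab <- function(rgb) {
  lin <- numeric(3)
  for (k in 1:3) {
    v <- rgb[k] / 255
    lin[k] <- if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
  }
  M <- rbind(
    c(0.4124564, 0.3575761, 0.1804375),
    c(0.2126729, 0.7151522, 0.0721750),
    c(0.0193339, 0.1191920, 0.9503041)
  )
  xyz <- as.numeric(M %*% lin) / c(0.95047, 1, 1.08883)
  f <- numeric(3)
  for (k in 1:3) {
    f[k] <- if (xyz[k] > (6 / 29)^3) xyz[k]^(1 / 3) else xyz[k] / (3 * (6 / 29)^2) + 4 / 29
  }
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

# Exhaustive between-class-variance sweep for Otsu.
oracle_otsu <- function(values) {
  values <- round(values)
  best_t <- NA_integer_
  best_v <- -1
  n <- length(values)
  for (t in 0:255) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  list(threshold = best_t, between_class_variance = best_v)
}

# GLCM by explicit pixel-pair loops (symmetric, normalized).
oracle_glcm <- function(gray, mask = NULL, levels = 4, distance = 1, angle = 0) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  q <- pmin(floor(gray * levels / 256), levels - 1)
  off <- switch(as.character(angle),
    "0" = c(0, distance),
    "45" = c(-distance, distance),
    "90" = c(-distance, 0),
    "135" = c(-distance, -distance)
  )
  C <- matrix(0, levels, levels)
  for (r in seq_len(nrow(gray))) {
    for (cc in seq_len(ncol(gray))) {
      r2 <- r + off[1]
      c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(gray) || c2 < 1 || c2 > ncol(gray)) next
      if (!mask[r, cc] || !mask[r2, c2]) next
      i <- q[r, cc] + 1
      j <- q[r2, c2] + 1
      C[i, j] <- C[i, j] + 1
      C[j, i] <- C[j, i] + 1
    }
  }
  C / sum(C)
}

# GLCM statistics by explicit double loops.
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  con <- dis <- hom <- asm <- mx <- my <- 0
  for (i in 1:L) {
    for (j in 1:L) {
      con <- con + P[i, j] * (i - j)^2
      dis <- dis + P[i, j] * abs(i - j)
      hom <- hom + P[i, j] / (1 + abs(i - j))
      asm <- asm + P[i, j]^2
      mx <- mx + (i - 1) * P[i, j]
      my <- my + (j - 1) * P[i, j]
    }
  }
  vx <- vy <- cxy <- 0
  for (i in 1:L) {
    for (j in 1:L) {
      vx <- vx + (i - 1 - mx)^2 * P[i, j]
      vy <- vy + (j - 1 - my)^2 * P[i, j]
      cxy <- cxy + (i - 1) * (j - 1) * P[i, j]
    }
  }
  corr <- if (vx * vy > 0) (cxy - mx * my) / sqrt(vx * vy) else 1
  c(
    contrast = con, dissimilarity = dis, homogeneity = hom,
    energy = sqrt(asm), correlation = corr, ASM = asm
  )
}

# Direct (non-separable) 2-D convolution with mirror padding, loops only.
oracle_conv2d <- function(m, kernel) {
  k <- (nrow(kernel) - 1) %/% 2
  nr <- nrow(m)
  nc <- ncol(m)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) {
    for (cc in 1:nc) {
      acc <- 0
      for (u in -k:k) {
        for (v in -k:k) {
          acc <- acc + kernel[u + k + 1, v + k + 1] *
            m[refl(r + u, nr), refl(cc + v, nc)]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# A bright ellipse on a dark field, drawn from the equation.
draw_ellipse_image <- function(H = 64, W = 64, cy = H / 2, cx = W / 2,
                               ra = W / 3, rb = H / 4, fg = 180, bg = 30) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- ((xx - cx) / ra)^2 + ((yy - cy) / rb)^2 <= 1
  gray <- matrix(bg, H, W)
  gray[mask] <- fg
  list(gray = gray, mask = mask)
}

gray_to_rgb <- function(gray) {
  array(rep(gray, 3), dim = c(nrow(gray), ncol(gray), 3))
}

# Small labelled Gaussian feature tables for classifier tests.
make_gaussian_classes <- function(n_per_class = 20, p = 2, dist = 8, sd = 1,
                                  seed = 1, k = 3) {
  withr::with_seed(seed, {
    centers <- matrix(0, k, p)
    for (i in seq_len(k)) centers[i, 1:min(2, p)] <- dist * c(cos(2 * pi * i / k), sin(2 * pi * i / k))[1:min(2, p)]
    X <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n_per_class * p, sd = sd), n_per_class, p) +
        matrix(centers[i, ], n_per_class, p, byrow = TRUE)
    }))
    colnames(X) <- paste0("f", seq_len(p))
    tibble::as_tibble(X) |>
      tibble::add_column(
        label = rep(paste0("class", seq_len(k)), each = n_per_class),
        sample_id = sprintf("s%03d", seq_len(k * n_per_class)),
        .before = 1
      )
  })
}

# Shared small synthetic dataset (built once per test run).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(3, seed = 42)
    }
    cache
  }
})
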