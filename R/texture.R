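#' Gray-level co-occurrence matrix under a mask
#'
#' Counts pairs of quantized gray levels at the given offset, keeping only
#' pairs with both endpoints inside the mask, symmetrizes (each pair is
#' counted in both directions) and normalizes to probabilities. Gray
#' values 0--255 are uniformly quantized to `levels` bins
#' (`bin = floor(g * levels / 256)`).
#'
#' @param gray numeric matrix on the 0--255 scale.
#' @param mask logical matrix; defaults to all pixels.
#' @param levels number of gray levels after quantization (>= 2).
#' @param distance offset length in pixels.
#' @param angle offset direction in degrees: one of 0, 45, 90, 135.
#' @return A list of class `glcm_matrix` with elements `P` (levels x
#'   levels probability matrix), `levels`, `distance`, `angle`.
#' @export
compute_glcm <- function(gray, mask = NULL, levels = 32, distance = 1, angle = 0) {
  stopifnot(levels >= 2, distance >= 1)
  if (!angle %in% c(0, 45, 90, 135)) {
    rlang::abort("`angle` must be one of 0, 45, 90, 135 degrees.")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(gray), ncol(gray))
  }
  mask <- as_binary_mask(mask)
  q <- floor(pmin(pmax(gray, 0), 255) * levels / 256)
  q <- pmin(q, levels - 1)
  d <- as.integer(distance)
  # row/col offset of the neighbour (image rows grow downward; 45 deg is
  # up-right, 90 deg straight up, 135 deg up-left)
  off <- switch(as.character(angle),
    "0" = c(0L, d),
    "45" = c(-d, d),
    "90" = c(-d, 0L),
    "135" = c(-d, -d)
  )
  nr <- nrow(gray)
  nc <- ncol(gray)
  r0 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (!length(r0) || !length(c0)) {
    rlang::abort("Offset larger than the image: no valid pixel pairs.")
  }
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- mask[r0, c0, drop = FALSE] & mask[r0 + off[1], c0 + off[2], drop = FALSE]
  if (!any(ok)) {
    rlang::abort("No pixel pair has both endpoints inside the mask.")
  }
  idx <- a[ok] * levels + b[ok] # 0-based (i, j) -> flat
  counts <- tabulate(idx + 1L, nbins = levels * levels)
  C <- matrix(counts, levels, levels, byrow = TRUE)
  P <- C + t(C)
  P <- P / sum(P)
  structure(
    list(P = P, levels = levels, distance = distance, angle = angle),
    class = "glcm_matrix"
  )
}

#' GLCM texture statistics
#'
#' The six co-occurrence statistics used as texture categories:
#' contrast `sum P (i-j)^2`, dissimilarity `sum P |i-j|`, homogeneity
#' `sum P / (1 + |i-j|)` (inverse difference), ASM `sum P^2`, energy
#' `sqrt(ASM)`, and correlation (defined as 1 when either marginal
#' standard deviation is zero, i.e. a constant texture is perfectly
#' self-correlated).
#'
#' @param glcm a `glcm_matrix` from [compute_glcm()], or a bare
#'   normalized probability matrix.
#' @return A one-row tibble with columns `contrast`, `dissimilarity`,
#'   `homogeneity`, `energy`, `correlation`, `ASM`.
#' @export
glcm_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm_matrix")) glcm$P else as.matrix(glcm)
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  mu_x <- sum(i * P)
  mu_y <- sum(j * P)
  var_x <- sum((i - mu_x)^2 * P)
  var_y <- sum((j - mu_y)^2 * P)
  sxsy <- sqrt(var_x * var_y)
  corr <- if (sxsy > 0) (sum(i * j * P) - mu_x * mu_y) / sxsy else 1
  asm <- sum(P^2)
  tibble::tibble(
    contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + abs(i - j))),
    energy = sqrt(asm),
    correlation = corr,
    ASM = asm
  )
}

# GLCM features averaged over the four standard angles.
glcm_features_avg <- function(gray, mask = NULL, levels = 32, distance = 1,
                              angles = c(0, 45, 90, 135)) {
  feats <- purrr::map(
    angles,
    function(a) glcm_features(compute_glcm(gray, mask, levels, distance, a))
  )
  dplyr::summarise(dplyr::bind_rows(feats), dplyr::across(dplyr::everything(), mean))
}

#' The sixteen Law's 5 x 5 texture kernels
#'
#' Outer products of the classic 1-D vectors L5 (level) = (1,4,6,4,1),
#' E5 (edge) = (-1,-2,0,2,1), S5 (spot) = (-1,0,2,0,-1) and R5 (ripple)
#' = (1,-4,6,-4,1). The kernel named `XY` is `outer(X, Y)`: `X` runs
#' along rows (vertical direction), `Y` along columns.
#'
#' @return A named list of 16 matrices in the order L5L5, L5E5, L5S5,
#'   L5R5, E5L5, ..., R5R5.
#' @export
laws_kernels <- function() {
  v <- list(
    L5 = c(1, 4, 6, 4, 1),
    E5 = c(-1, -2, 0, 2, 1),
    S5 = c(-1, 0, 2, 0, -1),
    R5 = c(1, -4, 6, -4, 1)
  )
  out <- list()
  for (a in names(v)) {
    for (b in names(v)) {
      out[[paste0(a, b)]] <- outer(v[[a]], v[[b]])
    }
  }
  out
}

laws_vectors <- function() {
  list(
    L5 = c(1, 4, 6, 4, 1),
    E5 = c(-1, -2, 0, 2, 1),
    S5 = c(-1, 0, 2, 0, -1),
    R5 = c(1, -4, 6, -4, 1)
  )
}

# Law's energy maps: local-mean removal, separable convolution with each
# kernel (mirror padding), then a 15 x 15 moving average of the absolute
# response. Returns a named list of 16 energy matrices.
laws_energy_maps <- function(gray, window = 15L) {
  k <- (window - 1L) %/% 2L
  g <- gray - box_mean(gray, k)
  v <- laws_vectors()
  out <- list()
  for (a in names(v)) {
    rowpass <- conv1d(g, v[[a]], dim = 1L)
    for (b in names(v)) {
      resp <- conv1d(rowpass, v[[b]], dim = 2L)
      out[[paste0(a, b)]] <- box_mean(abs(resp), k)
    }
  }
  out
}

#' Law's texture energy features
#'
#' Pipeline: (1) subtract the 15 x 15 local mean (illumination removal);
#' (2) convolve with each of the 16 Law's kernels (mirror padding);
#' (3) average the absolute response over a 15 x 15 window (energy map);
#' (4) report the mean of each energy map over the mask eroded by 7 px,
#' so every contributing window is fully interior to the foreground.
#'
#' @param gray numeric matrix on the 0--255 scale.
#' @param mask logical foreground mask.
#' @param window energy/averaging window size (odd, default 15).
#' @return A one-row tibble with columns `e_L5L5` ... `e_R5R5` (paper
#'   order), all non-negative.
#' @export
laws_features <- function(gray, mask, window = 15L) {
  mask <- as_binary_mask(mask)
  k <- (window - 1L) %/% 2L
  core <- erode_mask(mask, k)
  if (!any(core)) {
    rlang::abort("Mask too small: no interior pixels after erosion for the Law's window.")
  }
  maps <- laws_energy_maps(gray, window)
  vals <- purrr::map_dbl(maps, function(m) mean(m[core]))
  tibble::as_tibble(as.list(rlang::set_names(vals, paste0("e_", names(maps)))))
}

#' All 22 texture categories of a seed image
#'
#' Six GLCM statistics (averaged over the 0/45/90/135 degree offsets at
#' the given distance) followed by the sixteen Law's texture energies.
#'
#' @param img a [seed_image()], or a grayscale matrix (0--255).
#' @param mask logical foreground mask; defaults to the mask stored in
#'   `img`, if any.
#' @param levels,distance GLCM quantization levels and offset distance.
#' @param window Law's energy window.
#' @return A one-row tibble: `sample_id`, `label`, the 6 GLCM columns,
#'   then `e_L5L5` ... `e_R5R5`.
#' @export
texture_features <- function(img, mask = NULL, levels = 32, distance = 1,
                             window = 15L) {
  if (inherits(img, "seed_image")) {
    gray <- to_gray(img)
    if (is.null(mask)) mask <- img$mask
  } else {
    gray <- img
  }
  if (is.null(mask)) {
    rlang::abort("A foreground mask is required (none supplied or stored).")
  }
  meta <- seed_meta(img)
  dplyr::bind_cols(
    tibble::tibble(sample_id = meta$sample_id, label = meta$label),
    glcm_features_avg(gray, mask, levels, distance),
    laws_features(gray, mask, window)
  )
}

# Column names of the 22 texture categories, paper order.
texture_feature_names <- function() {
  c(
    "contrast", "dissimilarity", "homogeneity", "energy", "correlation", "ASM",
    paste0("e_", names(laws_kernels()))
  )
}

# Column names of the 9 colour categories.
color_feature_names <- function() {
  paste0("mean_", c("R", "G", "B", "Lstar", "astar", "bstar", "H", "S", "I"))
}
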