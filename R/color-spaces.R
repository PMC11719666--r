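#' Convert an RGB image to CIELAB
#'
#' Standard sRGB decoding (piecewise gamma with the 0.04045 threshold),
#' D65 reference white, 2 degree observer, and the CIE `f(t)` with
#' `delta = 6/29`. `L*` lies in \[0, 100\]; `a*` and `b*` are signed chroma
#' axes (green--red and blue--yellow).
#'
#' @param img a [seed_image()] or H x W x 3 array on the 0--255 scale.
#' @return An H x W x 3 array of (L*, a*, b*).
#' @export
rgb_to_lab <- function(img) {
  px <- as_pixel_array(img) / 255
  lin <- ifelse(px <= 0.04045, px / 12.92, ((px + 0.055) / 1.055)^2.4)
  r <- lin[, , 1]
  g <- lin[, , 2]
  b <- lin[, , 3]
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  xr <- X / 0.95047
  yr <- Y / 1.0
  zr <- Z / 1.08883
  eps <- (6 / 29)^3
  f <- function(t) ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xr)
  fy <- f(yr)
  fz <- f(zr)
  out <- array(0, dim = dim(px))
  # the 7-digit matrix constants can push pure white microscopically
  # past 100; clamp so the stated L* range holds exactly
  out[, , 1] <- pmin(pmax(116 * fy - 16, 0), 100)
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  out
}

#' Convert a CIELAB triple to sRGB
#'
#' Inverse of [rgb_to_lab()] (D65, 2 degree observer). Out-of-gamut values
#' are clipped to \[0, 255\]. Used by the synthetic generator to realise a
#' target seed-coat colour.
#'
#' @param L,a,b CIELAB coordinates (vectors of equal length).
#' @return A matrix with columns R, G, B on the 0--255 scale.
#' @export
lab_to_rgb <- function(L, a, b) {
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  delta <- 6 / 29
  finv <- function(t) ifelse(t > delta, t^3, 3 * delta^2 * (t - 4 / 29))
  X <- 0.95047 * finv(fx)
  Y <- 1.0 * finv(fy)
  Z <- 1.08883 * finv(fz)
  r <- 3.2404542 * X - 1.5371385 * Y - 0.4985314 * Z
  g <- -0.9692660 * X + 1.8760108 * Y + 0.0415560 * Z
  bl <- 0.0556434 * X - 0.2040259 * Y + 1.0572252 * Z
  gam <- function(v) {
    v <- pmin(pmax(v, 0), 1)
    ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
  }
  cbind(R = gam(r), G = gam(g), B = gam(bl)) * 255
}

#' Convert an RGB image to HSI
#'
#' Hue--saturation--intensity with `I = (R + G + B) / 3` on the 0--255
#' scale, `S = 1 - 3 min(R, G, B) / (R + G + B)`, and hue in degrees
#' \[0, 360) from the arccos formula, reflected (`H = 360 - theta`) when
#' `B > G`. Conventions for degenerate pixels: `S = 0` when
#' `R + G + B = 0`, and `H = 0` whenever `S = 0`.
#'
#' @param img a [seed_image()] or H x W x 3 array on the 0--255 scale.
#' @return An H x W x 3 array of (H, S, I).
#' @export
rgb_to_hsi <- function(img) {
  px <- as_pixel_array(img)
  r <- px[, , 1]
  g <- px[, , 2]
  b <- px[, , 3]
  total <- r + g + b
  i <- total / 3
  s <- ifelse(total > 0, 1 - 3 * pmin(r, g, b) / total, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ratio <- ifelse(den > 0, num / den, 1)
  theta <- acos(pmin(pmax(ratio, -1), 1)) * 180 / pi
  h <- ifelse(b > g, 360 - theta, theta)
  h[s == 0] <- 0
  out <- array(0, dim = dim(px))
  out[, , 1] <- h
  out[, , 2] <- s
  out[, , 3] <- i
  out
}

#' Foreground colour features of a seed image
#'
#' Means and population standard deviations of the nine colour channels
#' (R, G, B, L*, a*, b*, H, S, I) over the foreground pixels. The hue mean
#' is circular (resultant of unit vectors, reported in degrees) and the
#' hue SD is the circular standard deviation in degrees. The nine means
#' are the colour feature categories used downstream; the SDs are
#' exported as auxiliary columns.
#'
#' @param img a [seed_image()] or H x W x 3 array on the 0--255 scale.
#' @param mask logical foreground mask; defaults to the mask stored in
#'   `img`, if any.
#' @return A one-row tibble: `sample_id`, `label`, `mean_R` ... `mean_I`,
#'   `sd_R` ... `sd_I`.
#' @export
color_features <- function(img, mask = NULL) {
  px <- as_pixel_array(img)
  if (is.null(mask) && inherits(img, "seed_image")) {
    mask <- img$mask
  }
  if (is.null(mask)) {
    rlang::abort("A foreground mask is required (none supplied or stored).")
  }
  mask <- as_binary_mask(mask)
  if (!identical(dim(mask), dim(px)[1:2])) {
    rlang::abort("`mask` must match the image height and width.")
  }
  if (!any(mask)) {
    rlang::abort("Empty mask: at least one foreground pixel is required.")
  }
  lab <- rgb_to_lab(px)
  hsi <- rgb_to_hsi(px)
  chan <- list(
    R = px[, , 1][mask], G = px[, , 2][mask], B = px[, , 3][mask],
    Lstar = lab[, , 1][mask], astar = lab[, , 2][mask], bstar = lab[, , 3][mask],
    H = hsi[, , 1][mask], S = hsi[, , 2][mask], I = hsi[, , 3][mask]
  )
  means <- purrr::map_dbl(chan, mean)
  sds <- purrr::map_dbl(chan, sd_pop)
  # hue is an angle: mean of unit vectors, circular SD
  hr <- chan$H * pi / 180
  mh <- atan2(mean(sin(hr)), mean(cos(hr))) * 180 / pi
  means[["H"]] <- (mh + 360) %% 360
  rbar <- sqrt(mean(sin(hr))^2 + mean(cos(hr))^2)
  sds[["H"]] <- if (rbar > 0) sqrt(pmax(-2 * log(rbar), 0)) * 180 / pi else Inf
  meta <- seed_meta(img)
  tibble::tibble(
    sample_id = meta$sample_id, label = meta$label,
    !!!rlang::set_names(as.list(means), paste0("mean_", names(means))),
    !!!rlang::set_names(as.list(sds), paste0("sd_", names(sds)))
  )
}

seed_meta <- function(img) {
  if (inherits(img, "seed_image")) {
    list(
      sample_id = img$sample_id %||% "sample",
      label = img$label %||% NA_character_
    )
  } else {
    list(sample_id = "sample", label = NA_character_)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
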