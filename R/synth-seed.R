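#' Default synthetic seed class parameters
#'
#' Three synthetic classes emulating the qualitative colour/texture
#' structure of genuine spine-date seed and its two counterfeits:
#' `synthHAS` is the brightest and smoothest, `synthZSS` is intermediate
#' in brightness with strong speckle, `synthZMS` is the darkest, reddest
#' and most strongly textured. Base colours are CIELAB triples; noise
#' amplitude is the foreground intensity SD of the band-limited noise,
#' smoothness its blur radius in px, speckle the fraction of foreground
#' pixels replaced by bright salt.
#'
#' @return A tibble with one row per class: `name`, `L`, `a`, `b`,
#'   `noise_amplitude`, `noise_smoothness`, `speckle_density`,
#'   `r_major_min`, `r_major_max`, `r_minor_min`, `r_minor_max`.
#' @export
synth_class_params <- function() {
  tibble::tibble(
    name = c("synthHAS", "synthZSS", "synthZMS"),
    L = c(65, 48, 38),
    a = c(18, 25, 32),
    b = c(30, 22, 35),
    noise_amplitude = c(4, 12, 18),
    noise_smoothness = c(3, 1, 1),
    speckle_density = c(0.00, 0.05, 0.02),
    r_major_min = 60, r_major_max = 85,
    r_minor_min = 40, r_minor_max = 60
  )
}

#' Generate one synthetic seed image
#'
#' Renders a dark background (per-pixel intensity 30 +/- 5), one filled
#' rotated ellipse coloured at the class's base CIELAB triple, additive
#' band-limited luminance noise on the foreground (white noise blurred
#' by `noise_smoothness`, rescaled to SD `noise_amplitude`), bright salt
#' speckle on a `speckle_density` fraction of foreground pixels, and a
#' mild vertical shading gradient (+/- 8 percent). Deterministic given
#' `seed`. The returned image carries the ground-truth ellipse mask.
#'
#' @param params a one-row slice of [synth_class_params()] (or a list
#'   with the same fields).
#' @param canvas integer (height, width), default c(256, 256).
#' @param seed integer RNG seed.
#' @param sample_id sample identifier.
#' @return A [seed_image()] with the ground-truth mask in `$mask` and the
#'   drawn ellipse pixel count in `attr(, "true_area")`.
#' @export
generate_seed_image <- function(params, canvas = c(256, 256), seed = 1,
                                sample_id = NULL) {
  p <- as.list(params)
  H <- canvas[1]
  W <- canvas[2]
  if (p$r_major_max * 2 >= min(H, W) - 20) {
    rlang::abort("Ellipse radii too large for the canvas.")
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_%06d", p$name, seed %% 1000000L)
  }
  withr::with_seed(as.integer(seed), {
    # background
    img <- array(0, dim = c(H, W, 3))
    bg <- matrix(stats::runif(H * W, 25, 35), H, W)
    for (k in 1:3) img[, , k] <- bg

    # ground-truth ellipse
    cy <- H / 2 + stats::runif(1, -8, 8)
    cx <- W / 2 + stats::runif(1, -8, 8)
    ra <- stats::runif(1, p$r_major_min, p$r_major_max)
    rb <- stats::runif(1, p$r_minor_min, p$r_minor_max)
    th <- stats::runif(1, 0, pi)
    yy <- matrix(seq_len(H), H, W) - cy
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    u <- cos(th) * xx + sin(th) * yy
    v <- -sin(th) * xx + cos(th) * yy
    mask <- (u / ra)^2 + (v / rb)^2 <= 1

    # base coat colour
    rgb0 <- lab_to_rgb(p$L, p$a, p$b)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[mask] <- rgb0[k]
      img[, , k] <- ch
    }

    # band-limited luminance noise on the foreground
    if (p$noise_amplitude > 0) {
      noise <- matrix(stats::rnorm(H * W), H, W)
      noise <- gaussian_blur(noise, p$noise_smoothness)
      noise <- noise / stats::sd(noise) * p$noise_amplitude
      for (k in 1:3) {
        ch <- img[, , k]
        ch[mask] <- ch[mask] + noise[mask]
        img[, , k] <- ch
      }
    }

    # bright salt speckle on the foreground
    if (p$speckle_density > 0) {
      fg_idx <- which(mask)
      n_salt <- round(length(fg_idx) * p$speckle_density)
      if (n_salt > 0) {
        salt <- sample(fg_idx, n_salt)
        for (k in 1:3) {
          ch <- img[, , k]
          ch[salt] <- 255
          img[, , k] <- ch
        }
      }
    }

    # vertical shading gradient, +/- 8 percent top to bottom
    shade <- 1 + 0.08 * seq(-1, 1, length.out = H)
    img <- img * array(shade, dim = c(H, W, 3))
    img <- pmin(pmax(img, 0), 255)

    out <- seed_image(img, mask = mask, label = p$name, sample_id = sample_id)
    attr(out, "true_area") <- sum(mask)
    out
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` images for each class in `params` with per-image
#' seeds derived deterministically from the master seed, and builds a
#' manifest. When `dir` is given, images and ground-truth masks are
#' written as PNGs and a `manifest.csv` alongside them.
#'
#' @param n_per_class images per class (or a vector, one count per
#'   class row of `params`).
#' @param seed master RNG seed.
#' @param params class parameter tibble, default [synth_class_params()].
#' @param canvas integer (height, width).
#' @param dir optional output directory for PNGs + manifest.csv.
#' @return A list of class `synth_dataset`: `images` (list of
#'   [seed_image()]), `manifest` (tibble `sample_id`, `label`, `path`,
#'   `true_area`), `params`, `seed`.
#' @export
generate_dataset <- function(n_per_class, seed = 42,
                             params = synth_class_params(),
                             canvas = c(256, 256), dir = NULL) {
  stopifnot(all(n_per_class >= 1))
  counts <- if (length(n_per_class) == 1) {
    rep(n_per_class, nrow(params))
  } else {
    stopifnot(length(n_per_class) == nrow(params))
    n_per_class
  }
  total <- sum(counts)
  seeds <- derive_seeds(seed, total)
  plan <- tibble::tibble(
    class_row = rep(seq_len(nrow(params)), counts),
    idx_in_class = unlist(lapply(counts, seq_len)),
    img_seed = seeds
  )
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("Cannot create output directory '%s'.", dir))
  }
  images <- purrr::pmap(plan, function(class_row, idx_in_class, img_seed) {
    p <- params[class_row, ]
    generate_seed_image(
      p,
      canvas = canvas, seed = img_seed,
      sample_id = sprintf("%s_%03d", p$name, idx_in_class)
    )
  })
  manifest <- tibble::tibble(
    sample_id = purrr::map_chr(images, "sample_id"),
    label = purrr::map_chr(images, "label"),
    path = NA_character_,
    true_area = purrr::map_dbl(images, function(x) attr(x, "true_area"))
  )
  if (!is.null(dir)) {
    manifest$path <- file.path(dir, paste0(manifest$sample_id, ".png"))
    purrr::walk2(images, manifest$path, write_seed_png)
    purrr::walk2(
      images, file.path(dir, paste0(manifest$sample_id, "_mask.png")),
      function(img, p) write_mask_png(img$mask, p)
    )
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(
    list(images = images, manifest = manifest, params = params, seed = seed),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d images (%s), master seed %d\n",
    length(x$images),
    paste(sprintf("%s: %d", names(table(x$manifest$label)), table(x$manifest$label)),
      collapse = ", "
    ),
    x$seed
  ))
  invisible(x)
}
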