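#' Per-pixel fire score map
#'
#' Fuses the nine colour channels into one score per pixel: each channel
#' is normalized to \[0, 1\] by its natural range (R, G, B, I by /255;
#' L* by /100; a*, b* by (v + 128)/255; H by /360; S as is) and the map
#' is their unweighted mean. Channel weights are configurable; the
#' default equal weighting is the minimal-assumption fusion and is
#' monotone in brightness.
#'
#' @param img a [seed_image()] or H x W x 3 array on the 0--255 scale.
#' @param weights optional named or positional vector of 9 non-negative
#'   channel weights (order R, G, B, L*, a*, b*, H, S, I); they are
#'   renormalized to sum to 1.
#' @return An H x W matrix with values in \[0, 1\].
#' @export
fire_score_map <- function(img, weights = NULL) {
  px <- as_pixel_array(img)
  H <- dim(px)[1]
  W <- dim(px)[2]
  lab <- rgb_to_lab(px)
  hsi <- rgb_to_hsi(px)
  ch <- lapply(
    list(
      px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255,
      lab[, , 1] / 100,
      (lab[, , 2] + 128) / 255, (lab[, , 3] + 128) / 255,
      hsi[, , 1] / 360, hsi[, , 2], hsi[, , 3] / 255
    ),
    matrix, nrow = H, ncol = W
  )
  if (is.null(weights)) {
    weights <- rep(1, 9)
  }
  if (length(weights) != 9 || any(weights < 0) || sum(weights) == 0) {
    rlang::abort("`weights` must be 9 non-negative values with a positive sum.")
  }
  w <- weights / sum(weights)
  out <- matrix(0, H, W)
  for (k in seq_len(9)) {
    out <- out + w[k] * ch[[k]]
  }
  pmin(pmax(out, 0), 1)
}

#' Fire foreground chart
#'
#' Scales the [fire_score_map()] to 0--255, binarises it with
#' [otsu_threshold()] (bright class as foreground), keeps the largest
#' 8-connected component and fills its holes.
#'
#' @inheritParams fire_score_map
#' @return A logical H x W foreground mask.
#' @export
extract_fire_foreground <- function(img, weights = NULL) {
  m <- fire_score_map(img, weights) * 255
  ot <- otsu_threshold(m)
  clean_mask(round(m) > ot$threshold)
}

#' Fire value of a seed image
#'
#' The mean of the fire score map over the fire foreground: the scalar
#' fusion of the nine colour channels for one sample.
#'
#' @inheritParams fire_score_map
#' @param foreground optional precomputed fire foreground mask.
#' @return A scalar in \[0, 1\].
#' @export
fire_value <- function(img, weights = NULL, foreground = NULL) {
  map <- fire_score_map(img, weights)
  if (is.null(foreground)) {
    foreground <- extract_fire_foreground(img, weights)
  }
  foreground <- as_binary_mask(foreground)
  if (!any(foreground)) {
    rlang::abort("Empty fire foreground: fire value undefined.")
  }
  mean(map[foreground])
}

#' Per-pixel ice score map
#'
#' Sum of the fifteen zero-sum-kernel Law's energy maps (L5L5, a pure
#' luminance channel, is excluded from the map), min--max rescaled to
#' \[0, 1\].
#'
#' @param gray numeric matrix on the 0--255 scale.
#' @param window Law's energy window (odd, default 15).
#' @return An H x W matrix in \[0, 1\] with minimum 0 and maximum 1.
#' @export
ice_score_map <- function(gray, window = 15L) {
  maps <- laws_energy_maps(gray, window)
  maps <- maps[setdiff(names(maps), "L5L5")]
  total <- Reduce(`+`, maps)
  rng <- range(total)
  if (rng[2] - rng[1] <= 1e-12) {
    rlang::abort("Degenerate input: flat texture energy (constant image).")
  }
  (total - rng[1]) / (rng[2] - rng[1])
}

#' Ice foreground chart
#'
#' Binarises the [ice_score_map()] (scaled to 0--255) with Otsu and
#' cleans the result (largest 8-connected component, hole fill).
#'
#' @inheritParams ice_score_map
#' @return A logical H x W foreground mask.
#' @export
extract_ice_foreground <- function(gray, window = 15L) {
  m <- ice_score_map(gray, window) * 255
  ot <- otsu_threshold(m)
  clean_mask(round(m) > ot$threshold)
}

#' Ice value of a seed image
#'
#' The scalar fusion of the 22 texture categories over the foreground:
#' `ice = (1/22) * (contrast/(L-1)^2 + dissimilarity/(L-1) + homogeneity
#' + energy + ASM + (correlation + 1)/2 + sum of the 16 Law's ratio
#' terms)`, where each Law's energy is self-normalized as
#' `e / (e + e_L5L5 + 1e-12)` so that a single image has a well-defined
#' value without batch-dependent scaling. Every term lies in \[0, 1\],
#' hence so does the ice value.
#'
#' @param gray numeric matrix on the 0--255 scale.
#' @param mask logical foreground mask.
#' @param levels,distance GLCM parameters (see [compute_glcm()]).
#' @param window Law's energy window.
#' @return A scalar in \[0, 1\].
#' @export
ice_value <- function(gray, mask, levels = 32, distance = 1, window = 15L) {
  g <- glcm_features_avg(gray, mask, levels, distance)
  l <- laws_features(gray, mask, window)
  eps <- 1e-12
  e0 <- l$e_L5L5
  ratios <- purrr::map_dbl(
    as.list(l),
    function(e) e / (e + e0 + eps)
  )
  terms <- c(
    g$contrast / (levels - 1)^2,
    g$dissimilarity / (levels - 1),
    g$homogeneity,
    g$energy,
    g$ASM,
    (g$correlation + 1) / 2,
    ratios
  )
  sum(terms) / 22
}

#' Fire-ice foreground chart pair
#'
#' The paired binary rasters shown for each sample: the colour-driven
#' fire foreground and the texture-driven ice foreground.
#'
#' @param img a [seed_image()] or H x W x 3 array (0--255).
#' @param weights optional fire channel weights.
#' @param window Law's energy window.
#' @return A list of class `fire_ice_chart` with logical elements
#'   `fire_fg` and `ice_fg` of the image's shape.
#' @export
fire_ice_chart <- function(img, weights = NULL, window = 15L) {
  structure(
    list(
      fire_fg = extract_fire_foreground(img, weights),
      ice_fg = extract_ice_foreground(to_gray(img), window)
    ),
    class = "fire_ice_chart"
  )
}

#' Reduce a labelled image set to the fire-ice table
#'
#' Runs the full fusion per sample: fire foreground and fire value from
#' the colour channels, seed foreground and ice value from the texture
#' features. Samples whose extraction fails are skipped with a warning
#' naming the sample and reason.
#'
#' @param dataset a synthetic dataset from [generate_dataset()], a
#'   manifest tibble with columns `sample_id`, `label`, `path`, or a
#'   list of [seed_image()] objects.
#' @param weights optional fire channel weights.
#' @param levels,distance,window texture parameters.
#' @return A tibble with one row per sample: `sample_id`, `label`,
#'   `fire`, `ice`.
#' @export
reduce_dataset <- function(dataset, weights = NULL, levels = 32, distance = 1,
                           window = 15L) {
  images <- dataset_images(dataset)
  rows <- purrr::map(images, function(img) {
    tryCatch(
      {
        fire <- fire_value(img, weights)
        fg <- img$mask %||% extract_foreground(img)
        ice <- ice_value(to_gray(img), fg, levels, distance, window)
        meta <- seed_meta(img)
        tibble::tibble(
          sample_id = meta$sample_id, label = meta$label,
          fire = fire, ice = ice
        )
      },
      error = function(e) {
        rlang::warn(sprintf(
          "Skipping sample '%s': %s",
          seed_meta(img)$sample_id, conditionMessage(e)
        ))
        NULL
      }
    )
  })
  dplyr::bind_rows(rows)
}

# Accept the three dataset forms used across the pipeline.
dataset_images <- function(dataset) {
  if (inherits(dataset, "synth_dataset")) {
    return(dataset$images)
  }
  if (is.data.frame(dataset)) {
    if (!all(c("sample_id", "path") %in% names(dataset))) {
      rlang::abort("Manifest must have `sample_id` and `path` columns.")
    }
    return(purrr::pmap(
      list(
        dataset$path, dataset$sample_id,
        if ("label" %in% names(dataset)) dataset$label else NA_character_
      ),
      function(p, id, lab) read_seed_image(p, label = lab, sample_id = id)
    ))
  }
  if (is.list(dataset) && all(purrr::map_lgl(dataset, inherits, "seed_image"))) {
    return(dataset)
  }
  rlang::abort("`dataset` must be a synth_dataset, a manifest tibble, or a list of seed_image objects.")
}
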