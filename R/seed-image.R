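#' Seed image container
#'
#' A `seed_image` is the unit of feature extraction: an H x W x 3 array of
#' 8-bit RGB intensities (stored as doubles on the 0--255 scale), an optional
#' binary foreground mask, an optional class label and a sample id.
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 255\].
#' @param mask optional logical H x W matrix marking foreground pixels.
#' @param label optional class label (character scalar).
#' @param sample_id sample identifier (character scalar).
#'
#' @return An object of class `seed_image`.
#' @export
seed_image <- function(pixels, mask = NULL, label = NULL, sample_id = "sample") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    rlang::abort("`pixels` must be an H x W x 3 array.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    rlang::abort("`pixels` must lie in [0, 255] with no missing values.")
  }
  if (!is.null(mask)) {
    mask <- as_binary_mask(mask)
    if (!identical(dim(mask), dim(pixels)[1:2])) {
      rlang::abort("`mask` must match the image height and width.")
    }
  }
  structure(
    list(pixels = pixels, mask = mask, label = label, sample_id = sample_id),
    class = "seed_image"
  )
}

#' @export
print.seed_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<seed_image> %s: %d x %d px%s%s\n",
    x$sample_id, d[1], d[2],
    if (!is.null(x$label)) paste0(", label=", x$label) else "",
    if (!is.null(x$mask)) sprintf(", mask (%d fg px)", sum(x$mask)) else ""
  ))
  invisible(x)
}

#' Read a seed photograph
#'
#' Decodes a PNG or TIFF file into a [seed_image()]. Pixels are returned in
#' RGB channel order on the 0--255 scale whatever the on-disk layout;
#' 16-bit inputs are rescaled to 8-bit, grayscale and paletted images are
#' expanded to RGB with a warning, and an alpha channel is dropped.
#'
#' @param path path to an image file (PNG, JPEG or TIFF).
#' @param label,sample_id optional metadata attached to the result;
#'   `sample_id` defaults to the file name without extension.
#'
#' @return A [seed_image()].
#' @export
read_seed_image <- function(path, label = NULL, sample_id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Image file does not exist: '%s'", path))
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      rlang::abort(sprintf("Cannot decode image '%s': %s", path, conditionMessage(e)))
    }
  )
  px <- EBImage::imageData(img) # values in [0,1], dims x,y[,c]
  if (length(dim(px)) == 2L) {
    rlang::warn(sprintf("'%s' is not RGB; replicating the gray channel.", path))
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3] > 3L) {
    px <- px[, , 1:3, drop = FALSE] # drop alpha
  } else if (dim(px)[3] < 3L) {
    rlang::warn(sprintf("'%s' has %d channels; replicating to RGB.", path, dim(px)[3]))
    px <- array(px[, , rep(1L, 3L)], dim = c(dim(px)[1:2], 3L))
  }
  # EBImage stores x (column) as the first dimension; transpose to rows x cols
  px <- aperm(px, c(2L, 1L, 3L))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  }
  seed_image(px * 255, label = label, sample_id = sample_id)
}

#' Write a binary mask as a single-channel PNG
#'
#' Background is written as 0, foreground as 255.
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' Write a seed image as an 8-bit RGB PNG
#'
#' @param img a [seed_image()] or H x W x 3 array on the 0--255 scale.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_seed_png <- function(img, path) {
  px <- as_pixel_array(img)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

# Coerce seed_image or raw array to the H x W x 3 [0,255] array.
as_pixel_array <- function(img) {
  if (inherits(img, "seed_image")) {
    return(img$pixels)
  }
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
    return(img)
  }
  rlang::abort("Expected a `seed_image` or an H x W x 3 array.")
}

as_binary_mask <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
  } else {
    m <- mask > 0
  }
  storage.mode(m) <- "logical"
  m
}

#' Luminance grayscale of an RGB image
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`, on the 0--255 scale.
#'
#' @param img a [seed_image()] or H x W x 3 array (0--255).
#' @return An H x W numeric matrix.
#' @export
to_gray <- function(img) {
  px <- as_pixel_array(img)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}
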