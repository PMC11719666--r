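#' Otsu threshold of a grayscale raster
#'
#' Exhaustive search over the 256 candidate cut points `t = 0 ... 255`
#' for the threshold maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the classes `{<= t}` and `{> t}`.
#' Ties are broken toward the smallest threshold. Pixels strictly above
#' the threshold form the bright class.
#'
#' @param gray numeric matrix on the 0--255 scale (values are rounded to
#'   integers for the histogram).
#' @return A list of class `otsu_result` with elements `threshold`
#'   (integer) and `between_class_variance`.
#' @export
otsu_threshold <- function(gray) {
  v <- round(as.numeric(gray))
  v <- pmin(pmax(v, 0), 255)
  if (length(unique(v)) < 2) {
    rlang::abort("Degenerate input: Otsu needs at least 2 distinct gray values.")
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  lv <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * lv)
  mt <- m0[256]
  w1 <- 1 - w0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mt - m0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  t_best <- which.max(bcv) - 1L # which.max takes the first (smallest) argmax
  structure(
    list(threshold = t_best, between_class_variance = bcv[t_best + 1L]),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf(
    "<otsu_result> threshold = %d, between-class variance = %.4f\n",
    x$threshold, x$between_class_variance
  ))
  invisible(x)
}

#' Extract the seed foreground of an image
#'
#' Converts to luminance grayscale (Rec. 601), binarises with
#' [otsu_threshold()] taking the bright class (pixels above the threshold)
#' as the candidate foreground, keeps only the largest 8-connected
#' component, and fills its holes.
#'
#' @param img a [seed_image()] or H x W x 3 array on the 0--255 scale.
#' @return A logical H x W foreground mask.
#' @export
extract_foreground <- function(img) {
  gray <- to_gray(img)
  ot <- otsu_threshold(gray)
  fg <- round(gray) > ot$threshold
  clean_mask(fg)
}
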