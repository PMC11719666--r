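#' Extract the full colour + texture feature table
#'
#' Runs foreground segmentation and both feature families per sample and
#' joins them into the 31-column feature table (9 colour means + 22
#' texture categories), with the colour SDs as auxiliary columns.
#' Samples whose extraction fails are skipped with a warning.
#'
#' @param dataset a `synth_dataset`, a manifest tibble (`sample_id`,
#'   `label`, `path`), or a list of [seed_image()] objects.
#' @param mask_source `"auto"` segments each image with
#'   [extract_foreground()]; `"truth"` uses the mask stored on the image
#'   (falling back to auto when absent).
#' @param levels,distance,window texture parameters.
#' @return A tibble: `sample_id`, `label`, `mean_R` ... `mean_I`, the 22
#'   texture columns, then `sd_R` ... `sd_I`.
#' @export
extract_features <- function(dataset, mask_source = c("auto", "truth"),
                             levels = 32, distance = 1, window = 15L) {
  mask_source <- match.arg(mask_source)
  images <- dataset_images(dataset)
  rows <- purrr::map(images, function(img) {
    tryCatch(
      {
        mask <- if (mask_source == "truth" && !is.null(img$mask)) {
          img$mask
        } else {
          extract_foreground(img)
        }
        cf <- color_features(img, mask)
        tf <- texture_features(img, mask, levels, distance, window)
        dplyr::bind_cols(
          cf[c("sample_id", "label", color_feature_names())],
          tf[texture_feature_names()],
          cf[paste0("sd_", c("R", "G", "B", "Lstar", "astar", "bstar", "H", "S", "I"))]
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

# The canonical analysis columns of a feature table: the 31 categories
# when present, otherwise every numeric column that is not an auxiliary
# SD or bookkeeping column.
feature_columns <- function(data, include_sd = FALSE) {
  canonical <- c(color_feature_names(), texture_feature_names())
  nm <- names(data)
  cols <- intersect(canonical, nm)
  if (!length(cols)) {
    cols <- nm[vapply(data, is.numeric, logical(1))]
    cols <- setdiff(cols, c("true_area", "img_seed"))
    if (!include_sd) cols <- cols[!startsWith(cols, "sd_")]
  } else if (include_sd) {
    cols <- c(cols, nm[startsWith(nm, "sd_")])
  }
  if (!length(cols)) rlang::abort("No numeric feature columns found.")
  cols
}

# Numeric feature matrix with sample ids as rownames.
feature_matrix <- function(data, columns = NULL) {
  if (is.null(columns)) columns <- feature_columns(data)
  X <- as.matrix(data[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  if ("sample_id" %in% names(data)) rownames(X) <- data$sample_id
  X
}

#' Write / read a feature table as CSV
#'
#' UTF-8, '.' decimal, one row per image, header included.
#'
#' @param data a feature tibble.
#' @param path CSV path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_features_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
}
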