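# Plain-text interchange: CSV manifests + 8-bit grayscale PNGs for image
# datasets, CSV for tabular datasets, YAML for feature specs.

#' Write a dataset to disk
#'
#' Tabular datasets become a single `samples.csv`; image datasets become a
#' `manifest.csv` (sample_id, path, label, split) plus one 8-bit grayscale
#' PNG per sample with intensities mapped linearly to \[0, 1\].
#'
#' @param data A `ufm_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest/sample file path.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (dataset_modality(data) == "tabular3d") {
    path <- file.path(dir, "samples.csv")
    utils::write.csv(as.data.frame(data[, c("sample_id", "x", "y", "z",
                                            "label", "split",
                                            "is_carrier")]),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  rel <- file.path("images", paste0(data$sample_id, ".png"))
  for (i in seq_len(nrow(data))) {
    png::writePNG(data$pixels[[i]], file.path(dir, rel[i]))
  }
  manifest <- data.frame(sample_id = data$sample_id, path = rel,
                         label = data$label, split = data$split)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()] (or any PNG + CSV manifest)
#'
#' @param dir Directory containing `samples.csv` (tabular) or
#'   `manifest.csv` + PNGs (image).
#' @param n_classes Class count; inferred from the labels when omitted.
#' @return A `ufm_dataset`.
#' @export
read_dataset <- function(dir, n_classes = NULL) {
  tab <- file.path(dir, "samples.csv")
  man <- file.path(dir, "manifest.csv")
  if (file.exists(tab)) {
    df <- utils::read.csv(tab, stringsAsFactors = FALSE)
    nc <- n_classes %||% (max(df$label) + 1L)
    return(new_ufm_dataset(df, "tabular3d", nc,
                           provenance = list(generator = "read_dataset",
                                             dir = dir)))
  }
  if (!file.exists(man)) {
    abort(sprintf("no samples.csv or manifest.csv under %s.", dir),
          class = "ufm_invalid_argument")
  }
  df <- utils::read.csv(man, stringsAsFactors = FALSE)
  pixels <- lapply(df$path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 3)

      img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                   c(1, 2), mean)   # channel collapse by mean
    img
  })
  df$path <- NULL
  df$pixels <- pixels
  df$is_carrier <- df$is_carrier %||% FALSE
  nc <- n_classes %||% (max(df$label) + 1L)
  new_ufm_dataset(df, "image", nc, side = nrow(pixels[[1]]),
                  provenance = list(generator = "read_dataset", dir = dir))
}

#' Text-patch unique feature
#'
#' Convenience constructor: renders `text` with [render_text_patch()] and
#' wraps it as an image-patch [unique_feature()], remembering the text so
#' the feature can be serialised as a compact YAML spec.
#'
#' @param text Text to render (A-Z and space).
#' @param m Patch side; defaults to the smallest square that fits.
#' @param offset 0-based `(row, col)` anchor.
#' @param y_u Unique-feature label.
#' @param mode `"mask"` or `"opaque"`.
#' @return A `ufm_feature`.
#' @examples
#' text_feature("A", y_u = 1)
#' @export
text_feature <- function(text, m = NULL, offset = c(2L, 2L), y_u = 1L,
                         mode = "mask") {
  k <- nchar(text)
  m <- m %||% max(5L, 5L * k + (k - 1L))
  r <- render_text_patch(text, m)
  f <- unique_feature("image_patch", patch = r$patch, mask = r$mask,
                      offset = offset, y_u = y_u, mode = mode)
  f$text <- text
  f$m <- m
  f
}

#' Serialise a unique feature as YAML
#'
#' @param feature A [unique_feature()]; image-patch features must carry a
#'   `text` field (see [text_feature()]) so rendering stays reproducible.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature <- function(feature, path) {
  spec <- if (feature$kind == "z_value") {
    list(kind = "z_value", z_value = feature$z_value, y_u = feature$y_u,
         carrier_id = feature$carrier_id)
  } else {
    if (is.null(feature$text)) {
      abort("only text-based image features serialise to YAML; use text_feature().",
            class = "ufm_invalid_argument")
    }
    list(kind = "image_patch", text = feature$text, m = feature$m,
         offset = as.list(feature$offset), y_u = feature$y_u,
         carrier_id = feature$carrier_id, mode = feature$mode)
  }
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read a unique feature from a YAML spec
#'
#' @param path File written by [write_feature()].
#' @return A `ufm_feature`.
#' @export
read_feature <- function(path) {
  spec <- yaml::read_yaml(path)
  if (identical(spec$kind, "z_value")) {
    return(unique_feature("z_value", z_value = spec$z_value,
                          y_u = spec$y_u,
                          carrier_id = spec$carrier_id %||% NA_character_))
  }
  f <- text_feature(spec$text, m = spec$m,
                    offset = unlist(spec$offset), y_u = spec$y_u,
                    mode = spec$mode %||% "mask")
  f$carrier_id <- spec$carrier_id %||% NA_character_
  f
}
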