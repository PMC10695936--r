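#' Describe a unique feature
#'
#' A unique feature is a feature occurring in exactly one training sample:
#' either an image patch (a glyph rendering with its binary mask, anchored at
#' a 0-based `offset` from the top-left corner) or a distinguished z-axis
#' value for 3-D tabular data. `y_u` records the unique-feature label: the
#' class of the single carrier sample.
#'
#' @param kind `"image_patch"` or `"z_value"`.
#' @param patch,mask m x m numeric patch and logical glyph mask
#'   (image_patch), e.g. from [render_text_patch()].
#' @param offset Integer `(row, col)` 0-based top-left anchor of the patch.
#' @param z_value The carrier's z value (z_value kind).
#' @param y_u Integer label of the carrier sample.
#' @param carrier_id `sample_id` of the carrier (may be `NA` before
#'   planting).
#' @param mode `"mask"` (default: only glyph pixels overwrite the image) or
#'   `"opaque"` (the full patch square overwrites, background included).
#' @return An object of class `ufm_feature`.
#' @export
unique_feature <- function(kind = c("image_patch", "z_value"),
                           patch = NULL, mask = NULL, offset = c(2L, 2L),
                           z_value = NULL, y_u = 1L,
                           carrier_id = NA_character_,
                           mode = c("mask", "opaque")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (kind == "image_patch") {
    if (is.null(patch)) {
      abort("an image_patch feature needs `patch`.",
            class = "ufm_invalid_argument")
    }
    if (is.null(mask)) mask <- patch > 0
    stopifnot(is.matrix(patch), is.matrix(mask),
              all(dim(patch) == dim(mask)), nrow(patch) == ncol(patch))
    offset <- as.integer(offset)
    if (length(offset) != 2 || any(offset < 0)) {
      abort("`offset` must be two non-negative integers (row, col).",
            class = "ufm_invalid_argument")
    }
  } else if (is.null(z_value)) {
    abort("a z_value feature needs `z_value`.", class = "ufm_invalid_argument")
  }
  structure(
    list(kind = kind, patch = patch, mask = mask, offset = offset,
         z_value = z_value, y_u = as.integer(y_u),
         carrier_id = carrier_id, mode = mode),
    class = "ufm_feature"
  )
}

#' @export
print.ufm_feature <- function(x, ...) {
  if (x$kind == "image_patch") {
    cat(sprintf("<ufm_feature> image patch %dx%d at offset (%d,%d), %d mask px, y_u = %d\n",
                nrow(x$patch), ncol(x$patch), x$offset[1], x$offset[2],
                sum(x$mask), x$y_u))
  } else {
    cat(sprintf("<ufm_feature> z value %.3g, y_u = %d\n", x$z_value, x$y_u))
  }
  invisible(x)
}

check_footprint <- function(feature, side) {
  m <- nrow(feature$patch)
  if (any(feature$offset + m > side)) {
    abort(sprintf("patch footprint (offset %d,%d + %d) exceeds image side %d.",
                  feature$offset[1], feature$offset[2], m, side),
          class = "ufm_invalid_argument")
  }
  if (m >= side) {
    abort("patch side must be smaller than the image side.",
          class = "ufm_invalid_argument")
  }
  invisible(TRUE)
}

#' Inject a unique feature into samples
#'
#' Image-patch features overwrite the pixels under the glyph mask with the
#' patch foreground (or the full patch square in `"opaque"` mode), leaving
#' every pixel outside the footprint untouched; z-value features set the z
#' coordinate. Labels and sample ids are unchanged and injection is
#' idempotent.
#'
#' @param x An image matrix, a length-3 numeric `(x, y, z)`, or a dataset
#'   tibble (every row is injected).
#' @param feature A [unique_feature()].
#' @return Object of the same shape as `x`.
#' @export
inject_feature <- function(x, feature) UseMethod("inject_feature")

#' @export
inject_feature.matrix <- function(x, feature) {
  stopifnot(feature$kind == "image_patch")
  check_footprint(feature, nrow(x))
  m <- nrow(feature$patch)
  rows <- feature$offset[1] + seq_len(m)
  cols <- feature$offset[2] + seq_len(m)
  sub <- x[rows, cols]
  if (feature$mode == "mask") {
    sub[feature$mask] <- feature$patch[feature$mask]
  } else {
    sub <- feature$patch
  }
  x[rows, cols] <- sub
  x
}

#' @export
inject_feature.numeric <- function(x, feature) {
  stopifnot(feature$kind == "z_value", length(x) == 3)
  x[3] <- feature$z_value
  x
}

#' @export
inject_feature.data.frame <- function(x, feature) {
  if (feature$kind == "z_value") {
    x$z <- rep(feature$z_value, nrow(x))
  } else {
    x$pixels <- lapply(x$pixels, inject_feature, feature = feature)
  }
  x
}

#' Overlay a constant rectangle on an image
#'
#' Sets every pixel of the rectangle to `intensity` (default 0, a black box).
#' Used to equalise a patch region across the non-carrier images, e.g. the
#' sanitisation-style protocol where one training image keeps a name and all
#' others get a black rectangle of the same size.
#'
#' @param x An image matrix or a dataset tibble (every row is overlaid).
#' @param offset 0-based `(row, col)` of the rectangle's top-left corner.
#' @param shape `(height, width)` of the rectangle.
#' @param intensity Fill value in \[0, 1\].
#' @return Same shape as `x`.
#' @export
overlay_rectangle <- function(x, offset, shape, intensity = 0) {
  UseMethod("overlay_rectangle")
}

#' @export
overlay_rectangle.matrix <- function(x, offset, shape, intensity = 0) {
  offset <- as.integer(offset); shape <- as.integer(shape)
  if (any(offset < 0) || any(offset + shape > dim(x))) {
    abort("rectangle exceeds the image bounds.",
          class = "ufm_invalid_argument")
  }
  x[offset[1] + seq_len(shape[1]), offset[2] + seq_len(shape[2])] <- intensity
  x
}

#' @export
overlay_rectangle.data.frame <- function(x, offset, shape, intensity = 0) {
  x$pixels <- lapply(x$pixels, overlay_rectangle,
                     offset = offset, shape = shape, intensity = intensity)
  x
}

#' Corrupt an image-patch feature by removing glyph pixels
#'
#' Clears `k_removed` glyph pixels from the feature's mask. The removal order
#' is a random permutation of the mask pixels fixed by `order_seed`, so the
#' removed sets are nested: the pixels removed at `k` are a subset of those
#' removed at `k + 1`. Removed pixels simply revert to the underlying clean
#' image at injection time. Used to measure how sharply the M score tracks
#' the verbatim feature.
#'
#' @param feature An image-patch [unique_feature()].
#' @param k_removed Number of glyph pixels to clear, in `[0, sum(mask)]`.
#' @param order_seed Seed fixing the removal order.
#' @return The corrupted `ufm_feature`.
#' @export
corrupt_patch <- function(feature, k_removed, order_seed = 0L) {
  stopifnot(inherits(feature, "ufm_feature"))
  if (feature$kind != "image_patch") {
    abort("only image_patch features can be pixel-corrupted.",
          class = "ufm_invalid_argument")
  }
  n_mask <- sum(feature$mask)
  if (k_removed < 0 || k_removed > n_mask) {
    abort(sprintf("`k_removed` must lie in [0, %d].", n_mask),
          class = "ufm_invalid_argument")
  }
  if (k_removed == 0) return(feature)
  idx <- which(feature$mask)
  order <- withr::with_seed(as.integer(order_seed), sample(idx))
  feature$mask[order[seq_len(k_removed)]] <- FALSE
  feature
}

# Scan a dataset's images for exact occurrences of the feature's glyph
# pattern (mask pixels matching the patch foreground at some anchor).
# Returns the number of matching images; the uniqueness contract asks for 1.
find_feature_occurrences <- function(data, feature) {
  stopifnot(feature$kind == "image_patch")
  m <- nrow(feature$patch)
  fg <- feature$patch[feature$mask]
  hits <- map_lgl(data$pixels, function(img) {
    side <- nrow(img)
    for (r in 0:(side - m)) {
      for (cc in 0:(side - m)) {
        sub <- img[r + seq_len(m), cc + seq_len(m)]
        if (all(abs(sub[feature$mask] - fg) < 1e-12)) return(TRUE)
      }
    }
    FALSE
  })
  sum(hits)
}
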