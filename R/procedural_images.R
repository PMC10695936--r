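#' Generate a procedural image-classification dataset
#'
#' A download-free stand-in for small image benchmarks: single-channel
#' square images whose class is decided by a learnable global property --
#' the orientation of a noisy sinusoidal grating. Class `k` (0-based)
#' centres its orientation on `k * 180 / n_classes` degrees, with per-image
#' orientation jitter, wavelength, phase, contrast and pixel noise, so the
#' class signal is global and imperfect (a competent classifier reaches
#' high but not saturated accuracy -- real benchmarks leave probability
#' headroom, and an audit needs it too).
#'
#' The textured object sits away from the top-left corner: pixels in the
#' top-left margin are a constant dark background in every image, the
#' analogue of the empty corners of centred-object benchmarks. A patch
#' injected there is therefore an instance of a *rare concept* -- a region
#' the data never varies in. Intensities lie in \[0, 1\].
#'
#' Samples are split 70/15/15 into train/val/test with disjoint ids, and
#' generation is bit-identical per seed.
#'
#' @param n_classes Number of texture classes (>= 2).
#' @param n_per_class Samples per class.
#' @param side Image side length in pixels (>= 12, so a 5x5 patch plus
#'   margin fits).
#' @param seed Integer seed.
#' @return A `ufm_dataset` tibble with a `pixels` list-column.
#' @examples
#' imgs <- generate_procedural_images(n_classes = 2, n_per_class = 20,
#'                                    side = 16, seed = 1)
#' range(imgs$pixels[[1]])
#' @export
generate_procedural_images <- function(n_classes = 2L, n_per_class = 100L,
                                       side = 28L, seed = 0L) {
  if (side < 12) {
    abort("`side` must be >= 12 to host a 5x5 patch plus margin.",
          class = "ufm_invalid_argument")
  }
  if (n_classes < 2) {
    abort("`n_classes` must be >= 2.", class = "ufm_invalid_argument")
  }
  n <- n_classes * n_per_class
  margin <- max(3L, min(7L, side - 9L))   # constant top-left background band
  obj <- (margin + 1L):side               # textured object region
  osz <- length(obj)
  coords_r <- matrix(seq_len(osz), osz, osz)
  coords_c <- matrix(seq_len(osz), osz, osz, byrow = TRUE)

  withr::with_seed(as.integer(seed), {
    label <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    theta <- label * pi / n_classes + runif(n, -pi / 12, pi / 12)
    wavelength <- runif(n, 3.5, 7)
    phase <- runif(n, 0, 2 * pi)
    amplitude <- runif(n, 0.2, 0.35)
    noise <- matrix(rnorm(n * osz * osz, 0, 0.15), n)
    ord <- sample.int(n)
    split <- rep("train", n)
    n_val <- round(0.15 * n); n_test <- round(0.15 * n)
    idx <- sample.int(n)
    if (n_val > 0) split[idx[seq_len(n_val)]] <- "val"
    if (n_test > 0) split[idx[n_val + seq_len(n_test)]] <- "test"
  })

  pixels <- lapply(seq_len(n), function(i) {
    u <- coords_c * cos(theta[i]) + coords_r * sin(theta[i])
    tex <- 0.55 + amplitude[i] * sin(2 * pi * u / wavelength[i] + phase[i]) +
      matrix(noise[i, ], osz, osz)
    img <- matrix(0, side, side)
    img[obj, obj] <- pmin(pmax(tex, 0), 1)
    img
  })

  df <- tibble(
    sample_id = sprintf("im%05d", seq_len(n)),
    label = label, split = split, is_carrier = FALSE,
    pixels = pixels
  )[ord, ]
  df$sample_id <- sprintf("im%05d", seq_len(n))  # ids follow shuffled order

  new_ufm_dataset(
    df, modality = "image", n_classes = n_classes, side = side,
    provenance = list(generator = "procedural_images", seed = as.integer(seed),
                      n_classes = n_classes, n_per_class = n_per_class,
                      side = side)
  )
}

#' Plant a unique feature on one training image
#'
#' Injects `feature` into a single randomly chosen training image of class
#' `feature$y_u` and records it as the carrier. Optionally overlays a
#' constant rectangle over the feature footprint on every *other* image
#' (train, val and test), the sanitisation-style protocol that equalises the
#' patch region across non-carriers.
#'
#' @param data An image `ufm_dataset`.
#' @param feature An image-patch [unique_feature()].
#' @param seed Seed for the carrier choice.
#' @param overlay_others If `TRUE`, non-carrier images get a rectangle of
#'   the patch's size at the patch's offset, filled with `overlay_intensity`.
#' @param overlay_intensity Fill intensity for the overlay (default 0).
#' @return A list with `dataset` (carrier planted) and `feature`
#'   (`carrier_id` filled in).
#' @export
plant_carrier <- function(data, feature, seed = 0L, overlay_others = FALSE,
                          overlay_intensity = 0) {
  stopifnot(dataset_modality(data) == "image",
            feature$kind == "image_patch")
  check_footprint(feature, dataset_side(data))
  cand <- which(data$split == "train" & data$label == feature$y_u)
  if (length(cand) == 0) {
    abort("no training image of class y_u to carry the feature.",
          class = "ufm_empty_selection")
  }
  ci <- withr::with_seed(as.integer(seed), sample(cand, 1L))
  if (overlay_others) {
    m <- nrow(feature$patch)
    data$pixels <- lapply(data$pixels, overlay_rectangle,
                          offset = feature$offset, shape = c(m, m),
                          intensity = overlay_intensity)
  }
  data$pixels[[ci]] <- inject_feature(data$pixels[[ci]], feature)
  data$is_carrier <- seq_len(nrow(data)) == ci
  feature$carrier_id <- data$sample_id[ci]
  list(dataset = data, feature = feature)
}
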