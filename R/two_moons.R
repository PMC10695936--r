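#' Generate a 3-D "two moons" dataset with a rare z-axis feature
#'
#' Two interleaving half-circle classes live in the x-y plane; the z axis
#' carries no class information and models a *rare concept*: a direction of
#' the input space that the data never (setting i) or only noisily
#' (setting ii) explores. Exactly one training sample of class
#' `carrier_label` -- the carrier -- receives `z = carrier_z`, making its z
#' value a unique feature in the sense of a feature that occurs in a single
#' training sample.
#'
#' The x-y geometry, the split assignment and the carrier choice depend only
#' on `seed`, not on `z_mode`: calling the generator twice with the same seed
#' under `z_mode = "zeros"` and `z_mode = "gaussian"` yields datasets that
#' differ only in the z background, which is what a matched rare-concept
#' comparison needs.
#'
#' @param n Total number of samples (>= 4). Split 70/15/15 into
#'   train/val/test; the carrier is always placed in the training split.
#' @param noise_xy Standard deviation of the isotropic Gaussian noise added
#'   to the moon coordinates.
#' @param z_mode `"zeros"` (z = 0 everywhere; the z direction is unexplored)
#'   or `"gaussian"` (z ~ N(0, z_sigma^2); the concept is no longer rare,
#'   only the carrier's value is).
#' @param z_sigma Scale of the Gaussian z background (used when
#'   `z_mode = "gaussian"`).
#' @param carrier_z z value given to the single carrier sample.
#' @param carrier_label Class (0 or 1) the carrier is drawn from.
#' @param carrier If `FALSE`, no carrier is planted (a null dataset for
#'   calibration experiments); the returned feature is still the z-value
#'   feature an auditor would probe with, but `carrier_id` is `NA`.
#' @param seed Integer seed controlling every random draw.
#' @return A list with elements `dataset` (a [tibble][tibble::tibble] of
#'   class `ufm_dataset` with columns sample_id, x, y, z, label, split,
#'   is_carrier) and `feature` (a `ufm_feature` of kind `"z_value"`).
#' @examples
#' tm <- generate_two_moons_3d(n = 200, seed = 1)
#' table(tm$dataset$split)
#' sum(tm$dataset$is_carrier)
#' @export
generate_two_moons_3d <- function(n = 1000, noise_xy = 0.1,
                                  z_mode = c("zeros", "gaussian"),
                                  z_sigma = 0.1, carrier_z = 1,
                                  carrier_label = 1L, carrier = TRUE,
                                  seed = 0L) {
  z_mode <- match.arg(z_mode)
  if (n < 4) {
    abort("`n` must be at least 4.", class = "ufm_invalid_argument")
  }
  if (!carrier_label %in% c(0L, 1L)) {
    abort("`carrier_label` must be 0 or 1.", class = "ufm_invalid_argument")
  }
  if (z_mode == "gaussian" && z_sigma <= 0) {
    abort("`z_sigma` must be > 0 for gaussian z.",
          class = "ufm_invalid_argument")
  }

  withr::with_seed(as.integer(seed), {
    n1 <- n %/% 2L
    n0 <- n - n1
    t0 <- seq(0, pi, length.out = n0)
    t1 <- seq(0, pi, length.out = n1)
    x <- c(cos(t0), 1 - cos(t1)) + rnorm(n, 0, noise_xy)
    y <- c(sin(t0), 1 - sin(t1) - 0.5) + rnorm(n, 0, noise_xy)
    label <- c(rep(0L, n0), rep(1L, n1))

    ord <- sample.int(n)
    x <- x[ord]; y <- y[ord]; label <- label[ord]

    n_val <- round(0.15 * n)
    n_test <- round(0.15 * n)
    split <- rep("train", n)
    idx <- sample.int(n)
    if (n_val > 0) split[idx[seq_len(n_val)]] <- "val"
    if (n_test > 0) split[idx[n_val + seq_len(n_test)]] <- "test"

    ci <- sample(which(label == carrier_label), 1L)
    if (split[ci] != "train") {
      swap <- which(split == "train")[1L]
      split[c(ci, swap)] <- split[c(swap, ci)]
    }

    # z drawn last so zeros/gaussian runs share identical xy and carrier
    z <- if (z_mode == "zeros") rep(0, n) else rnorm(n, 0, z_sigma)
  })

  is_carrier <- rep(FALSE, n)
  if (carrier) {
    z[ci] <- carrier_z
    is_carrier[ci] <- TRUE
  }

  ids <- sprintf("tm%05d", seq_len(n))
  df <- tibble(
    sample_id = ids, x = x, y = y, z = z,
    label = label, split = split, is_carrier = is_carrier
  )
  dataset <- new_ufm_dataset(
    df, modality = "tabular3d", n_classes = 2L,
    provenance = list(generator = "two_moons_3d", seed = as.integer(seed),
                      n = n, noise_xy = noise_xy, z_mode = z_mode,
                      z_sigma = z_sigma, carrier_z = carrier_z,
                      carrier_label = as.integer(carrier_label),
                      carrier = carrier)
  )
  feature <- unique_feature(
    kind = "z_value", z_value = carrier_z,
    y_u = as.integer(carrier_label),
    carrier_id = if (carrier) ids[ci] else NA_character_
  )
  list(dataset = dataset, feature = feature)
}
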