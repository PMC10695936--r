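#' Build aligned clean/injected sample pairs for sensitivity measurement
#'
#' Every selected sample yields a pair: the original (clean) sample and the
#' same sample with the unique feature injected. Pairs differ only inside
#' the feature footprint (the patch rectangle, or the z coordinate), which
#' is what lets the mean likelihood difference be attributed to the feature.
#'
#' @param data A `ufm_dataset`.
#' @param feature A [unique_feature()].
#' @param label_filter An integer label to restrict pairs to, or `"all"`.
#' @param exclude_carrier Drop the carrier sample from the selection.
#' @param split Restrict to one split (`"train"`, `"val"`, `"test"`) or
#'   `NULL` for the whole dataset (e.g. an external reference set).
#' @return A tibble of class `ufm_pairs` with columns `sample_id`, `label`,
#'   `clean`, `injected` (list-columns of samples).
#' @export
make_paired_eval_set <- function(data, feature, label_filter = "all",
                                 exclude_carrier = TRUE, split = NULL) {
  sel <- rep(TRUE, nrow(data))
  if (!is.null(split)) sel <- sel & data$split == split
  if (!identical(label_filter, "all")) {
    sel <- sel & data$label == as.integer(label_filter)
  }
  if (exclude_carrier && !is.null(feature$carrier_id) &&
      !is.na(feature$carrier_id)) {
    sel <- sel & data$sample_id != feature$carrier_id
  }
  sub <- data[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort("no samples left after filtering; cannot build pairs.",
          class = "ufm_empty_selection")
  }
  modality <- dataset_modality(data)
  if (modality == "tabular3d") {
    clean <- pmap(list(sub$x, sub$y, sub$z), function(x, y, z) c(x, y, z))
  } else {
    check_footprint(feature, dataset_side(data))
    clean <- sub$pixels
  }
  injected <- lapply(clean, inject_feature, feature = feature)
  out <- tibble(sample_id = sub$sample_id, label = sub$label,
                clean = clean, injected = injected)
  class(out) <- c("ufm_pairs", class(out))
  attr(out, "modality") <- modality
  attr(out, "label_filter") <- label_filter
  attr(out, "n_classes") <- n_classes(data)
  out
}

# Stack the clean / injected samples of a pair set into feature matrices.
pairs_matrices <- function(pairs) {
  flat <- function(col) do.call(rbind, lapply(col, as.vector))
  list(clean = flat(pairs$clean), injected = flat(pairs$injected))
}

#' @export
print.ufm_pairs <- function(x, ...) {
  cat(sprintf("<ufm_pairs> %d %s pairs (label filter: %s)\n",
              nrow(x), attr(x, "modality"),
              paste(attr(x, "label_filter"), collapse = ",")))
  NextMethod()
}
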