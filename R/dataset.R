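# Labelled sample collections.
#
# A dataset is a tibble with one row per sample plus attributes describing the
# modality. Tabular (3-D) datasets carry numeric columns x, y, z; image
# datasets carry a `pixels` list-column of l x l matrices with intensities in
# [0, 1]. Shared columns: sample_id, label (0-based class index), split
# ("train"/"val"/"test"), is_carrier.

new_ufm_dataset <- function(df, modality, n_classes, side = NULL,
                            provenance = list()) {
  out <- as_tibble(df)
  class(out) <- c("ufm_dataset", class(out))
  attr(out, "modality") <- modality
  attr(out, "n_classes") <- as.integer(n_classes)
  attr(out, "side") <- if (is.null(side)) NULL else as.integer(side)
  attr(out, "provenance") <- provenance
  out
}

#' Number of classes of a dataset or model
#'
#' @param x A `ufm_dataset` or `ufm_model`.
#' @return Integer count of class labels.
#' @export
n_classes <- function(x) {
  nc <- attr(x, "n_classes") %||% x$n_classes
  if (is.null(nc)) abort("`x` carries no class count.")
  as.integer(nc)
}

dataset_modality <- function(data) {
  attr(data, "modality") %||%
    (if ("pixels" %in% names(data)) "image" else "tabular3d")
}

dataset_side <- function(data) {
  s <- attr(data, "side")
  if (is.null(s) && "pixels" %in% names(data) && nrow(data) > 0) {
    s <- nrow(data$pixels[[1]])
  }
  s
}

validate_dataset <- function(data) {
  req <- c("sample_id", "label", "split")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  nc <- n_classes(data)
  if (any(data$label < 0L | data$label >= nc)) {
    abort("dataset labels must lie in [0, n_classes).")
  }
  modality <- dataset_modality(data)
  if (modality == "tabular3d" && !all(c("x", "y", "z") %in% names(data))) {
    abort("tabular datasets need numeric columns x, y, z.")
  }
  if (modality == "image") {
    sides <- unique(map_int(data$pixels, nrow))
    if (length(sides) > 1) abort("all images must share the same side length.")
    rng <- range(unlist(lapply(data$pixels, range)))
    if (rng[1] < 0 || rng[2] > 1) abort("image intensities must lie in [0, 1].")
  }
  invisible(data)
}

# n x d feature matrix for the network: tabular -> (x, y, z); image -> one row
# per flattened (column-major) l x l image.
dataset_matrix <- function(data) {
  if (dataset_modality(data) == "tabular3d") {
    cbind(x = data$x, y = data$y, z = data$z)
  } else {
    do.call(rbind, lapply(data$pixels, as.vector))
  }
}

dataset_split <- function(data, split) {
  stopifnot(split %in% c("train", "val", "test"))
  data[data$split == split, , drop = FALSE]
}

#' @export
print.ufm_dataset <- function(x, ...) {
  cat(sprintf("<ufm_dataset> %s, %d samples, %d classes",
              dataset_modality(x), nrow(x), n_classes(x)))
  side <- dataset_side(x)
  if (!is.null(side)) cat(sprintf(", %dx%d px", side, side))
  cat("\n")
  NextMethod()
}

# Keep class/attributes across dplyr verbs that return data frames.
#' @export
`[.ufm_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attrs <- c("modality", "n_classes", "side", "provenance")
    for (a in attrs) attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}
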