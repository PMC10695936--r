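# YAML run configuration with schema validation, presets and run manifests.

config_schema <- list(
  top = c("experiment", "preset", "n_seeds", "seed", "data", "feature",
          "train", "audit", "out"),
  data = c("generator", "n", "noise_xy", "z_mode", "z_sigma", "carrier_z",
           "carrier_label", "carrier", "n_classes", "n_per_class", "side",
           "seed", "overlay_others", "dir"),
  feature = c("kind", "text", "m", "offset", "z_value", "y_u", "mode"),
  train = c("arch", "learning_rate", "batch_size", "max_epochs", "patience",
            "regulariser", "strength", "aug_shift", "aug_flip", "seed",
            "rollback", "hidden"),
  audit = c("setting", "pool", "alpha", "paired", "label_filter")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s) in ", where, ": ",
                 paste(sQuote(bad), collapse = ", ")),
          class = "ufm_config_error")
  }
}

#' Shipped experiment presets
#'
#' * `"table2-two-moons"`: the 1000-seed MLP-2 multiseed audit on the
#'   rare-z two-moons task.
#' * `"rarity-two-moons"`: the 500-seed-per-setting rare-concept
#'   comparison.
#' * `"fig4-two-moons"`: the 100-seed per-epoch training-dynamics curve.
#' * `"image-smoke"`: a 10-seed CNN-1 audit on procedural images with a
#'   5x5 'A' patch carrier.
#'
#' @param name Preset name.
#' @return A configuration list accepted by [load_config()].
#' @export
ufm_preset <- function(name) {
  presets <- list(
    "table2-two-moons" = list(
      experiment = "multiseed", n_seeds = 1000L,
      data = list(generator = "two_moons", n = 1000L, noise_xy = 0.1,
                  z_mode = "zeros", carrier_z = 1, carrier_label = 1L),
      train = list(arch = "MLP-2", learning_rate = 1e-3),
      audit = list(setting = "white", pool = "test", alpha = 0.05)
    ),
    "rarity-two-moons" = list(
      experiment = "rarity", n_seeds = 500L,
      data = list(generator = "two_moons", n = 1000L, noise_xy = 0.1,
                  z_sigma = 0.1, carrier_z = 1, carrier_label = 1L),
      train = list(arch = "MLP-2", learning_rate = 1e-3)
    ),
    "fig4-two-moons" = list(
      experiment = "dynamics", n_seeds = 100L,
      data = list(generator = "two_moons", n = 1000L, noise_xy = 0.1,
                  z_mode = "zeros", carrier_z = 1, carrier_label = 1L),
      train = list(arch = "MLP-2", learning_rate = 1e-3)
    ),
    "image-smoke" = list(
      experiment = "multiseed", n_seeds = 10L,
      data = list(generator = "procedural_images", n_classes = 2L,
                  n_per_class = 250L, side = 16L),
      feature = list(kind = "image_patch", text = "A", m = 5L,
                     offset = c(2L, 2L), y_u = 1L),
      train = list(arch = "CNN-1", learning_rate = 1e-3,
                   max_epochs = 15L, patience = 3L),
      audit = list(setting = "white", pool = "test", alpha = 0.05)
    )
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset ", sQuote(name), "; available: ",
                 paste(sQuote(names(presets)), collapse = ", ")),
          class = "ufm_config_error")
  }
  presets[[name]]
}

#' Load and validate a YAML experiment configuration
#'
#' Reads the file, merges it over its `preset` (if any), rejects unknown
#' keys at every level, and fills defaults (a full [train_config()], audit
#' setting `"white"`, test pool, alpha 0.05, seed 0).
#'
#' @param path YAML file, or a list already in configuration shape.
#' @return A validated configuration list of class `ufm_config`.
#' @export
load_config <- function(path) {
  # YAML 1.1 would resolve a bare `n` (a legitimate key here) to FALSE;
  # keep y/n/on/off literal while still parsing true/false as booleans
  handlers <- list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x
  )
  cfg <- if (is.list(path)) path else yaml::read_yaml(path, handlers = handlers)
  if (!is.null(cfg$preset)) {
    base <- ufm_preset(cfg$preset)
    cfg$preset <- NULL
    cfg <- modifyList(base, cfg)
  }
  check_keys(cfg, config_schema$top, "top level")
  for (sec in c("data", "feature", "train", "audit")) {
    if (!is.null(cfg[[sec]])) {
      check_keys(cfg[[sec]], config_schema[[sec]], sec)
    }
  }
  cfg$experiment <- cfg$experiment %||% "audit"
  if (!cfg$experiment %in% c("audit", "multiseed", "dynamics", "rarity",
                             "regsweep", "ablate", "boundary")) {
    abort(paste0("unknown experiment: ", sQuote(cfg$experiment)),
          class = "ufm_config_error")
  }
  cfg$seed <- cfg$seed %||% 0L
  cfg$n_seeds <- cfg$n_seeds %||% 10L
  tr <- cfg$train %||% list()
  tr$arch <- tr$arch %||% "MLP-2"
  tr$seed <- tr$seed %||% cfg$seed
  cfg$train <- unclass(do.call(train_config, tr))
  cfg$audit <- modifyList(
    list(setting = "white", pool = "test", alpha = 0.05, paired = FALSE),
    cfg$audit %||% list())
  structure(cfg, class = c("ufm_config", "list"))
}

#' Run manifest for reproducibility
#'
#' Records the tool version, a configuration hash, the seeds used and the
#' output inventory; [verify_manifest()] recomputes the hash from the
#' stored configuration and checks it.
#'
#' @param config Configuration list the run used.
#' @param seeds Integer seeds consumed.
#' @param outputs Character vector of output files.
#' @return A list of class `ufm_manifest`.
#' @export
run_manifest <- function(config, seeds = integer(0),
                         outputs = character(0)) {
  structure(
    list(tool = "ufm", version = as.character(packageVersion("ufm")),
         config = config, config_hash = hash_config(config),
         seeds = seeds, outputs = outputs,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "ufm_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `ufm_manifest` (or a list read back from JSON).
#' @export
verify_manifest <- function(manifest) {
  identical(hash_config(manifest$config), manifest$config_hash)
}

# hash the JSON serialisation, so the hash survives a JSON round trip
# (R type distinctions like integer vs double do not)
hash_config <- function(config) {
  rlang::hash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA)))
}
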