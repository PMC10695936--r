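# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A reasonably trained two-moons model with the rare-z carrier planted.
moons_fit <- function() {
  cached("moons_fit", function() {
    tm <- generate_two_moons_3d(n = 1000, seed = 11)
    cfg <- train_config(max_epochs = 60, patience = 5, seed = 4)
    fit <- train(build_model("MLP-2", 2, tm$dataset, seed = 4, config = cfg),
                 tm$dataset, cfg)
    list(data = tm$dataset, feature = tm$feature, fit = fit, config = cfg)
  })
}

# A small trained CNN on procedural images with an 'A'-patch carrier.
image_fit <- function() {
  cached("image_fit", function() {
    im <- generate_procedural_images(2, 60, side = 12, seed = 7)
    f <- text_feature("A", y_u = 1)
    pl <- plant_carrier(im, f, seed = 3)
    cfg <- train_config("CNN-1", max_epochs = 4, patience = 4, seed = 2)
    fit <- train(build_model("CNN-1", 2, pl$dataset, seed = 2, config = cfg),
                 pl$dataset, cfg)
    list(data = pl$dataset, feature = pl$feature, fit = fit, config = cfg)
  })
}

# A deterministic "model" whose class-1 probability equals the first input
# coordinate (clipped): lets tests pin exact probability tables.
prob_model <- function(n_classes = 2L, transform = NULL) {
  structure(list(n_classes = n_classes, transform = transform),
            class = "prob_model")
}

predict_proba.prob_model <- function(model, newdata) {
  X <- if (is.matrix(newdata)) newdata else do.call(rbind, lapply(newdata, as.vector))
  if (!is.null(model$transform)) X <- model$transform(X)
  p1 <- pmin(pmax(X[, 1], 0), 1)
  cbind(1 - p1, p1)
}

# Uniform-output model: P = 1/n_classes regardless of input.
constant_model <- function(n_classes = 2L) {
  structure(list(n_classes = n_classes,
                 input_spec = list(modality = "tabular3d", d = 3L)),
            class = "constant_model")
}

predict_proba.constant_model <- function(model, newdata) {
  X <- if (is.matrix(newdata)) newdata else do.call(rbind, lapply(newdata, as.vector))
  matrix(1 / model$n_classes, nrow(X), model$n_classes)
}

local({
  registerS3method("predict_proba", "prob_model", predict_proba.prob_model,
                   envir = asNamespace("ufm"))
  registerS3method("predict_proba", "constant_model",
                   predict_proba.constant_model, envir = asNamespace("ufm"))
})

# Minimal hand-rolled tabular dataset wrapper for edge-case tests.
tiny_tabular <- function(n = 20, split = "test", label = NULL, z = 0) {
  ufm:::new_ufm_dataset(
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      x = seq(0, 1, length.out = n), y = rev(seq(0, 1, length.out = n)),
      z = z,
      label = label %||% rep(c(0L, 1L), length.out = n),
      split = split, is_carrier = FALSE),
    "tabular3d", 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modify_cfg <- function(cfg, reg, strength) {
  cfg$regulariser <- reg
  cfg$strength <- strength
  cfg
}
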