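arch_default_lr <- c("MLP-1" = 3e-4, "MLP-2" = 1e-3, "CNN-1" = 1e-3,
                     "custom" = 1e-3)

#' Training configuration
#'
#' Collects the architecture tag, optimiser hyperparameters, the
#' early-stopping schedule and the (single) active regulariser for a
#' training run. Defaults follow the small-model setup: Adam with the
#' architecture's learning rate (MLP-1 3e-4, MLP-2 and CNN-1 1e-3), batch
#' size 128, at most 100 epochs with 5 patient epochs, and the weights of
#' the lowest-validation-loss epoch kept.
#'
#' @param arch `"MLP-1"`, `"MLP-2"`, `"CNN-1"` or `"custom"`.
#' @param learning_rate Adam learning rate (> 0); default per `arch`.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Consecutive epochs without a new validation-loss minimum
#'   before stopping (must be <= `max_epochs`).
#' @param regulariser One of `"none"`, `"dropout"`, `"augmentation"`,
#'   `"weight_decay"`, `"batch_norm"`; exactly one is active per run.
#' @param strength Regulariser strength: dropout rate (default 0.25) or L2
#'   weight-decay coefficient (default 1e-4); ignored otherwise.
#' @param aug_shift,aug_flip Augmentation menu: maximum pixel shift and
#'   whether label-safe horizontal flips are added.
#' @param seed Integer seed driving parameter initialisation, batch
#'   shuffling and dropout for the run.
#' @param rollback Keep the best-validation-epoch weights (`TRUE`, default)
#'   or the final-epoch weights.
#' @param hidden Hidden layer widths for `arch = "custom"` MLPs.
#' @return A list of class `ufm_train_config`.
#' @export
train_config <- function(arch = c("MLP-2", "MLP-1", "CNN-1", "custom"),
                         learning_rate = NULL, batch_size = 128L,
                         max_epochs = 100L, patience = 5L,
                         regulariser = c("none", "dropout", "augmentation",
                                         "weight_decay", "batch_norm"),
                         strength = NULL, aug_shift = 2L, aug_flip = FALSE,
                         seed = 0L, rollback = TRUE, hidden = NULL) {
  arch <- match.arg(arch)
  regulariser <- match.arg(regulariser)
  if (is.null(learning_rate)) learning_rate <- arch_default_lr[[arch]]
  if (learning_rate <= 0) {
    abort("`learning_rate` must be > 0.", class = "ufm_invalid_argument")
  }
  if (patience > max_epochs) {
    abort("`patience` must be <= `max_epochs`.",
          class = "ufm_invalid_argument")
  }
  if (is.null(strength)) {
    strength <- switch(regulariser, dropout = 0.25, weight_decay = 1e-4, 0)
  }
  structure(
    list(arch = arch, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         regulariser = regulariser, strength = strength,
         aug_shift = as.integer(aug_shift), aug_flip = aug_flip,
         seed = as.integer(seed), rollback = rollback, hidden = hidden),
    class = "ufm_train_config"
  )
}

#' Build a classifier
#'
#' Constructs one of the reference architectures with freshly initialised
#' parameters (uniform in +/- 1/sqrt(fan_in), controlled by `seed`):
#'
#' * `MLP-1`: Dense(512)-Dense(256)-Dense(128)-Dense(n_classes), ReLU hidden
#'   activations, softmax output.
#' * `MLP-2`: Dense(3)-Dense(32)-Dense(128)-Dense(128)-Dense(2) on 3-D
#'   input (the narrow first layer is deliberate: it bottlenecks the input
#'   so a rare input direction competes with the task signal).
#' * `CNN-1`: Conv(32, 3x3)-Conv(64, 3x3)-MaxPool(2x2)-Dense(128)-
#'   Dense(128)-Dense(n_classes).
#' * `custom`: an MLP with `config$hidden` widths.
#'
#' Dropout or batch normalisation layers are inserted after each hidden
#' dense layer when `config$regulariser` asks for them.
#'
#' @param arch Architecture tag (see [train_config()]).
#' @param n_classes Number of output classes.
#' @param input_spec Either an integer input dimension (tabular) or a list
#'   `list(modality = "image", side = l)`; a `ufm_dataset` also works.
#' @param seed Seed for parameter initialisation.
#' @param config Optional [train_config()] carrying the regulariser and
#'   custom widths.
#' @return A `ufm_model` honouring the classifier contract: softmax
#'   probability rows summing to one, deterministic in evaluation mode.
#' @export
build_model <- function(arch, n_classes, input_spec, seed = 0L,
                        config = NULL) {
  if (inherits(input_spec, "ufm_dataset")) {
    input_spec <- if (dataset_modality(input_spec) == "image") {
      list(modality = "image", side = dataset_side(input_spec))
    } else {
      list(modality = "tabular3d", d = 3L)
    }
  } else if (is.numeric(input_spec) && length(input_spec) == 1) {
    input_spec <- list(modality = "tabular3d", d = as.integer(input_spec))
  }
  reg <- if (is.null(config)) "none" else config$regulariser
  strength <- if (is.null(config)) 0 else config$strength
  if (reg == "augmentation" && input_spec$modality != "image") {
    abort("data augmentation is defined for image data only.",
          class = "ufm_invalid_argument")
  }

  hidden_block <- function(layers, d_in, d_out) {
    layers <- c(layers, list(nn_dense(d_in, d_out)))
    if (reg == "batch_norm") layers <- c(layers, list(nn_batchnorm(d_out)))
    layers <- c(layers, list(nn_relu()))
    if (reg == "dropout") layers <- c(layers, list(nn_dropout(strength)))
    layers
  }

  withr::with_seed(as.integer(seed), {
    if (arch %in% c("MLP-1", "MLP-2", "custom")) {
      d <- input_spec$d %||% (input_spec$side^2)
      widths <- switch(arch,
        "MLP-1" = c(512L, 256L, 128L),
        "MLP-2" = c(3L, 32L, 128L, 128L),
        "custom" = as.integer(config$hidden %||% c(32L, 32L))
      )
      if (arch == "MLP-2") {
        if (d != 3L) {
          abort("MLP-2 expects 3-D input.", class = "ufm_invalid_argument")
        }
        n_classes <- 2L
      }
      layers <- list()
      d_in <- d
      for (w in widths) {
        layers <- hidden_block(layers, d_in, w)
        d_in <- w
      }
      layers <- c(layers, list(nn_dense(d_in, n_classes)))
    } else if (arch == "CNN-1") {
      if (input_spec$modality != "image") {
        abort("CNN-1 expects image input.", class = "ufm_invalid_argument")
      }
      side <- input_spec$side
      c1 <- nn_conv(c(side, side, 1L), 32L)
      c2 <- nn_conv(c1$out_shape, 64L)
      mp <- nn_maxpool(c2$out_shape)
      d_flat <- prod(mp$out_shape)
      layers <- list(c1, nn_relu(), c2, nn_relu(), mp)
      layers <- hidden_block(layers, d_flat, 128L)
      layers <- hidden_block(layers, 128L, 128L)
      layers <- c(layers, list(nn_dense(128L, n_classes)))
    } else {
      abort(paste0("unknown architecture: ", arch),
            class = "ufm_invalid_argument")
    }
  })

  structure(
    list(arch = arch, n_classes = as.integer(n_classes),
         input_spec = input_spec, layers = layers, seed = as.integer(seed),
         trained = FALSE),
    class = "ufm_model"
  )
}

#' @export
print.ufm_model <- function(x, ...) {
  np <- sum(map_dbl(x$layers, function(l) {
    sum(map_dbl(nn_param_names(l), function(p) length(l[[p]])))
  }))
  cat(sprintf("<ufm_model> %s, %d classes, %s parameters%s\n",
              x$arch, x$n_classes, format(np, big.mark = ","),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

#' Class-probability predictions
#'
#' Evaluation-mode forward pass (dropout off, batch-norm running statistics):
#' deterministic for a fixed model state, softmax rows summing to one.
#'
#' @param model A `ufm_model`.
#' @param newdata A numeric matrix (one sample per row, flattened
#'   column-major for images), a `ufm_dataset`, or a list of samples.
#' @return An `n x n_classes` matrix of probabilities.
#' @export
predict_proba <- function(model, newdata) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.ufm_model <- function(model, newdata) {
  X <- if (is.matrix(newdata)) {
    newdata
  } else if (inherits(newdata, "data.frame")) {
    dataset_matrix(newdata)
  } else if (is.list(newdata)) {
    do.call(rbind, lapply(newdata, as.vector))
  } else {
    matrix(newdata, nrow = 1)
  }
  expected <- if (model$input_spec$modality == "image") {
    model$input_spec$side^2
  } else {
    model$input_spec$d
  }
  if (ncol(X) != expected) {
    abort(sprintf("input has %d features; the model expects %d.",
                  ncol(X), expected),
          class = "ufm_shape_mismatch")
  }
  nn_softmax(nn_forward(model$layers, X, training = FALSE)$out)
}

#' Train a classifier with Adam, cross-entropy and early stopping
#'
#' Minimises the cross-entropy on the training split with Adam, evaluating
#' the validation split after every epoch. Training stops when the
#' validation loss has not improved for `config$patience` consecutive
#' epochs, or at `config$max_epochs`; with `config$rollback` (default) the
#' returned model carries the weights of the lowest-validation-loss epoch.
#' One integer seed (`config$seed`) drives initialisation, batch shuffling,
#' dropout and augmentation, so identical configurations reproduce
#' identical histories bit for bit.
#'
#' @param model A `ufm_model` from [build_model()]; its parameters are the
#'   starting point.
#' @param data A `ufm_dataset` with train and val splits.
#' @param config A [train_config()].
#' @param callback Optional `function(epoch, model)` invoked after every
#'   epoch with the live (end-of-epoch) model state -- the hook the
#'   training-dynamics experiment uses.
#' @return A `ufm_fit`: list with `model` (trained), `history` (tibble of
#'   epoch, train_loss, val_loss, val_acc), `best_epoch`, and `config`.
#' @export
train <- function(model, data, config = train_config(), callback = NULL) {
  UseMethod("train")
}

#' @export
train.ufm_model <- function(model, data, config = train_config(),
                            callback = NULL) {
  if (!any(data$split == "val")) {
    abort("`data` must contain a val split for early stopping.",
          class = "ufm_invalid_argument")
  }
  nc <- model$n_classes
  if (any(data$label >= nc)) {
    abort("labels exceed the model's class count.",
          class = "ufm_invalid_argument")
  }
  tr <- dataset_split(data, "train")
  va <- dataset_split(data, "val")
  X <- dataset_matrix(tr); yl <- tr$label
  Xv <- dataset_matrix(va); yv <- va$label
  is_image <- model$input_spec$modality == "image"
  augment <- config$regulariser == "augmentation"
  wd <- if (config$regulariser == "weight_decay") config$strength else 0

  layers <- model$layers
  state <- nn_adam_init(layers)
  n <- nrow(X)
  best <- Inf; best_epoch <- 0L; since <- 0L
  best_snap <- nn_snapshot_params(layers)
  hist <- vector("list", config$max_epochs)
  t_step <- 0L

  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (s in seq(1L, n, by = config$batch_size)) {
        ix <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- X[ix, , drop = FALSE]
        if (augment) {
          Xb <- nn_augment_batch(Xb, model$input_spec$side,
                                 shift = config$aug_shift,
                                 flip = config$aug_flip)
        }
        fw <- nn_forward(layers, Xb, training = TRUE)
        P <- nn_softmax(fw$out)
        loss <- nn_xent_loss(P, yl[ix])
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d.", ep),
                class = "ufm_training_diverged", epoch = ep)
        }
        ep_loss <- ep_loss + loss * length(ix); ep_n <- ep_n + length(ix)
        D <- nn_xent_grad(P, yl[ix])
        grads <- nn_backward(layers, fw$caches, D)
        layers <- nn_update_bn_stats(layers, fw$caches)
        t_step <- t_step + 1L
        upd <- nn_adam_step(layers, grads, state, t_step,
                            config$learning_rate, weight_decay = wd)
        layers <- upd$layers; state <- upd$state
      }
      Pv <- nn_softmax(nn_forward(layers, Xv, training = FALSE)$out)
      val_loss <- nn_xent_loss(Pv, yv)
      if (!is.finite(val_loss)) {
        abort(sprintf("training diverged (non-finite validation loss) at epoch %d.", ep),
              class = "ufm_training_diverged", epoch = ep)
      }
      val_acc <- mean(max.col(Pv) - 1L == yv)
      hist[[ep]] <- c(epoch = ep, train_loss = ep_loss / ep_n,
                      val_loss = val_loss, val_acc = val_acc)
      if (!is.null(callback)) {
        live <- model; live$layers <- layers; live$trained <- TRUE
        callback(ep, live)
      }
      if (val_loss < best) {
        best <- val_loss; best_epoch <- ep; since <- 0L
        best_snap <- nn_snapshot_params(layers)
      } else {
        since <- since + 1L
        if (since >= config$patience) break
      }
    }
  })

  if (config$rollback) {
    layers <- nn_restore_params(layers, best_snap)
  }
  model$layers <- layers
  model$trained <- TRUE
  history <- as_tibble(do.call(rbind, hist[!map_lgl(hist, is.null)]))
  structure(
    list(model = model, history = history, best_epoch = best_epoch,
         config = config),
    class = "ufm_fit"
  )
}

#' @export
print.ufm_fit <- function(x, ...) {
  cat(sprintf(
    "<ufm_fit> %s: %d epochs, best epoch %d (val loss %.4f, val acc %.3f)\n",
    x$model$arch, nrow(x$history), x$best_epoch,
    x$history$val_loss[x$best_epoch], x$history$val_acc[x$best_epoch]))
  invisible(x)
}
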