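# Experiment orchestration: multi-seed audits, training dynamics, the
# concept-rarity comparison, the regularisation sweep, pixel ablation and
# decision-boundary export.

default_label_filter <- function(data, feature) {
  # Image audits follow the white-box definition literally (pairs share the
  # carrier's label). For the 3-D toy task the clean label-likelihoods of
  # the carrier's class saturate near 1, so the audit pools both classes:
  # the score then has headroom exactly where the decision flips matter.
  if (dataset_modality(data) == "image") feature$y_u else "all"
}

#' Audit one trained model for unique-feature memorisation
#'
#' Builds the evaluation pairs for the requested privacy setting and
#' computes the M score with its significance flag. The evaluation pool
#' defaults to the test split (avoiding ordinary train-set overconfidence);
#' `pool = "train"` audits the training subset instead.
#'
#' @param model A trained `ufm_model`.
#' @param data The audited model's dataset (used for white/grey pairs).
#' @param feature The [unique_feature()] under audit.
#' @param setting `"white"`, `"grey"` or `"black"`.
#' @param pool `"test"` or `"train"` evaluation pool.
#' @param alpha Significance level.
#' @param paired Use the paired significance test.
#' @param label_filter Label restriction for white-box pairs; defaults to
#'   the carrier's label for images and `"all"` for 3-D tabular data.
#' @param reference Reference `ufm_dataset` for the black-box setting.
#' @return A `ufm_mscore`.
#' @export
audit_model <- function(model, data, feature,
                        setting = c("white", "grey", "black"),
                        pool = c("test", "train"), alpha = 0.05,
                        paired = FALSE, label_filter = NULL,
                        reference = NULL) {
  setting <- match.arg(setting)
  pool <- match.arg(pool)
  if (setting == "black") {
    if (is.null(reference)) {
      abort("the black-box audit needs a `reference` dataset.",
            class = "ufm_invalid_argument")
    }
    return(m_black(model, reference, feature, alpha = alpha,
                   paired = paired))
  }
  if (setting == "white") {
    lf <- label_filter %||% default_label_filter(data, feature)
    pairs <- make_paired_eval_set(data, feature, label_filter = lf,
                                  exclude_carrier = TRUE, split = pool)
    res <- m_white(model, pairs, y_u = feature$y_u, alpha = alpha,
                   paired = paired)
    res$pool <- pool
    return(res)
  }
  labels <- seq_len(n_classes(model)) - 1L
  by_label <- lapply(labels, function(l) {
    make_paired_eval_set(data, feature, label_filter = l,
                         exclude_carrier = TRUE, split = pool)
  })
  names(by_label) <- labels
  res <- m_grey(model, by_label, alpha = alpha, paired = paired)
  res$pool <- pool
  res
}

#' Train and audit across many seeds
#'
#' Repeats build-train-audit for seeds `config$seed + 0 .. n_seeds - 1` on a
#' fixed dataset (the carrier and data stay the same; only training
#' stochasticity varies) and aggregates the memorisation flags. Diverged
#' runs are recorded and excluded from the aggregates.
#'
#' @param data Dataset with the unique feature already planted.
#' @param feature The planted [unique_feature()].
#' @param config A [train_config()]; `config$seed` is the base seed.
#' @param n_seeds Number of runs.
#' @inheritParams audit_model
#' @param progress Emit a progress message every 10 runs.
#' @return A `ufm_report`.
#' @export
run_multiseed <- function(data, feature, config = train_config(),
                          n_seeds = 10L, setting = "white", pool = "test",
                          alpha = 0.05, paired = FALSE, label_filter = NULL,
                          reference = NULL, progress = FALSE) {
  if (n_seeds < 1) {
    abort("`n_seeds` must be >= 1.", class = "ufm_invalid_argument")
  }
  results <- list(); seeds <- integer(0); n_failed <- 0L
  for (s in seq_len(n_seeds) - 1L) {
    seed_s <- config$seed + s
    cfg <- config; cfg$seed <- seed_s
    res <- tryCatch({
      model <- build_model(cfg$arch, n_classes(data), data, seed = seed_s,
                           config = cfg)
      fit <- train(model, data, cfg)
      audit_model(fit$model, data, feature, setting = setting, pool = pool,
                  alpha = alpha, paired = paired,
                  label_filter = label_filter, reference = reference)
    }, ufm_training_diverged = function(e) {
      warn(sprintf("seed %d diverged: %s", seed_s, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      results <- c(results, list(res)); seeds <- c(seeds, seed_s)
    }
    if (progress && (s + 1L) %% 10L == 0L) {
      inform(sprintf("  run %d/%d done", s + 1L, n_seeds))
    }
  }
  snapshot <- list(config = unclass(config), setting = setting, pool = pool,
                   alpha = alpha, paired = paired,
                   label_filter = label_filter,
                   data_provenance = attr(data, "provenance"))
  aggregate_runs(results, experiment = "multiseed", seeds = seeds,
                 n_failed = n_failed, config_snapshot = snapshot)
}

#' Memorisation per training epoch
#'
#' Trains `n_seeds` models without best-epoch rollback and audits the live
#' end-of-epoch state after every epoch, recording the fraction of runs
#' flagged memorised and the mean clean test accuracy across the runs still
#' training at that epoch.
#'
#' @inheritParams run_multiseed
#' @return A `ufm_report` whose `per_epoch` tibble holds the dynamics
#'   curve; `per_run` holds each run's final-epoch audit.
#' @export
run_training_dynamics <- function(data, feature, config = train_config(),
                                  n_seeds = 10L, pool = "test",
                                  alpha = 0.05, paired = FALSE,
                                  label_filter = NULL, progress = FALSE) {
  config$rollback <- FALSE   # per-epoch audits use the live trajectory
  te <- dataset_split(data, "test")
  Xte <- dataset_matrix(te)
  records <- list(); finals <- list(); seeds <- integer(0); n_failed <- 0L
  for (s in seq_len(n_seeds) - 1L) {
    seed_s <- config$seed + s
    cfg <- config; cfg$seed <- seed_s
    rows <- list()
    last <- NULL
    ok <- tryCatch({
      model <- build_model(cfg$arch, n_classes(data), data, seed = seed_s,
                           config = cfg)
      train(model, data, cfg, callback = function(ep, live) {
        a <- audit_model(live, data, feature, setting = "white",
                         pool = pool, alpha = alpha, paired = paired,
                         label_filter = label_filter)
        acc <- mean(max.col(predict_proba(live, Xte)) - 1L == te$label)
        rows[[ep]] <<- tibble(seed = seed_s, epoch = ep, score = a$score,
                              p_value = a$p_value, memorised = a$memorised,
                              test_accuracy = acc)
        last <<- a
      })
      TRUE
    }, ufm_training_diverged = function(e) {
      warn(sprintf("seed %d diverged: %s", seed_s, conditionMessage(e)))
      FALSE
    })
    if (ok) {
      records <- c(records, list(dplyr::bind_rows(rows)))
      finals <- c(finals, list(last)); seeds <- c(seeds, seed_s)
    } else {
      n_failed <- n_failed + 1L
    }
    if (progress && (s + 1L) %% 10L == 0L) {
      inform(sprintf("  run %d/%d done", s + 1L, n_seeds))
    }
  }
  per_epoch_raw <- dplyr::bind_rows(records)
  per_epoch <- per_epoch_raw |>
    group_by(.data$epoch) |>
    summarise(n_running = n(),
              proportion_memorised = mean(.data$memorised),
              mean_test_accuracy = mean(.data$test_accuracy),
              .groups = "drop")
  snapshot <- list(config = unclass(config), setting = "white", pool = pool,
                   alpha = alpha, paired = paired,
                   label_filter = label_filter,
                   data_provenance = attr(data, "provenance"))
  rep <- aggregate_runs(finals, experiment = "dynamics", seeds = seeds,
                        n_failed = n_failed, config_snapshot = snapshot)
  rep$per_epoch <- per_epoch
  rep$per_epoch_runs <- per_epoch_raw
  rep
}

#' Rare-concept comparison on the 3-D two-moons task
#'
#' Runs the same multi-seed white-box audit under two backgrounds for the z
#' axis: setting (i), z = 0 for every sample except one carrier at
#' `carrier_z` (the z direction is an unexplored, rare concept), and
#' setting (ii), Gaussian z noise for all samples with the same single
#' carrier (the concept is common, only the carrier's value is rare). The
#' two settings share the x-y geometry, the carrier and the training seeds;
#' they differ only in the z background. Reports both aggregates plus a
#' two-proportion z-test of the ordering.
#'
#' @param n_seeds Seeds per setting (>= 30 for a stable proportion).
#' @param z_sigma Gaussian z scale for setting (ii).
#' @param config A [train_config()] (MLP-2 defaults).
#' @param n,noise_xy,carrier_z,carrier_label Generator parameters, see
#'   [generate_two_moons_3d()].
#' @param data_seed Seed for the shared dataset.
#' @inheritParams run_multiseed
#' @return A list of class `ufm_rarity`: `setting_i`, `setting_ii`
#'   (reports), `proportion_difference`, and `p_value` of the one-sided
#'   two-proportion test.
#' @export
run_rarity_experiment <- function(n_seeds = 100L, z_sigma = 0.1,
                                  config = train_config(), n = 1000L,
                                  noise_xy = 0.1, carrier_z = 1,
                                  carrier_label = 1L, data_seed = 0L,
                                  alpha = 0.05, paired = FALSE,
                                  progress = FALSE) {
  gi <- generate_two_moons_3d(n = n, noise_xy = noise_xy, z_mode = "zeros",
                              carrier_z = carrier_z,
                              carrier_label = carrier_label,
                              seed = data_seed)
  gii <- generate_two_moons_3d(n = n, noise_xy = noise_xy,
                               z_mode = "gaussian", z_sigma = z_sigma,
                               carrier_z = carrier_z,
                               carrier_label = carrier_label,
                               seed = data_seed)
  ri <- run_multiseed(gi$dataset, gi$feature, config, n_seeds = n_seeds,
                      setting = "white", alpha = alpha, paired = paired,
                      progress = progress)
  ri$experiment <- "rarity_i"
  rii <- run_multiseed(gii$dataset, gii$feature, config, n_seeds = n_seeds,
                       setting = "white", alpha = alpha, paired = paired,
                       progress = progress)
  rii$experiment <- "rarity_ii"
  ki <- sum(ri$per_run$memorised); ni <- nrow(ri$per_run)
  kii <- sum(rii$per_run$memorised); nii <- nrow(rii$per_run)
  pt <- suppressWarnings(
    prop.test(c(ki, kii), c(ni, nii), alternative = "greater",
              correct = FALSE)
  )
  structure(
    list(setting_i = ri, setting_ii = rii,
         proportion_difference = ri$proportion_memorised -
           rii$proportion_memorised,
         p_value = pt$p.value),
    class = "ufm_rarity"
  )
}

#' @export
print.ufm_rarity <- function(x, ...) {
  cat(sprintf(
    "<ufm_rarity> memorised: %.1f%% (rare z) vs %.1f%% (gaussian z); diff %.1f pp, one-sided p = %.2g\n",
    100 * x$setting_i$proportion_memorised,
    100 * x$setting_ii$proportion_memorised,
    100 * x$proportion_difference, x$p_value))
  invisible(x)
}

#' Does regularisation prevent unique-feature memorisation?
#'
#' Runs a multi-seed audit once per regulariser (exactly one active per
#' run) and reports the maximum M score per cell, the quantity the
#' regularisation comparison tracks.
#'
#' @param data Dataset with the unique feature planted.
#' @param feature The planted feature.
#' @param base_config A [train_config()]; its regulariser field is
#'   overridden per sweep cell.
#' @param regularisers Character vector of regulariser tags.
#' @param n_seeds Runs per regulariser (default 10).
#' @param dataset_name,model_name Labels for the output table.
#' @inheritParams run_multiseed
#' @return A tibble of class `ufm_regsweep` with columns dataset, model,
#'   regularisation, max_M, proportion_memorised; full reports in
#'   `attr(, "reports")`.
#' @export
run_regularisation_sweep <- function(data, feature,
                                     base_config = train_config(),
                                     regularisers = c("none", "dropout",
                                                      "augmentation",
                                                      "weight_decay",
                                                      "batch_norm"),
                                     n_seeds = 10L, setting = "white",
                                     pool = "test", alpha = 0.05,
                                     paired = FALSE, label_filter = NULL,
                                     dataset_name = NULL,
                                     model_name = NULL,
                                     progress = FALSE) {
  dataset_name <- dataset_name %||%
    (attr(data, "provenance")$generator %||% "dataset")
  model_name <- model_name %||% base_config$arch
  reports <- list()
  rows <- lapply(regularisers, function(reg) {
    cfg <- base_config
    cfg$regulariser <- reg
    cfg$strength <- switch(reg, dropout = 0.25, weight_decay = 1e-4, 0)
    rep <- run_multiseed(data, feature, cfg, n_seeds = n_seeds,
                         setting = setting, pool = pool, alpha = alpha,
                         paired = paired, label_filter = label_filter,
                         progress = progress)
    rep$experiment <- paste0("regsweep_", reg)
    reports[[reg]] <<- rep
    tibble(dataset = dataset_name, model = model_name, regularisation = reg,
           max_M = rep$max_M,
           proportion_memorised = rep$proportion_memorised)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ufm_regsweep", class(out))
  attr(out, "reports") <- reports
  out
}

#' M score under progressive feature-pixel removal
#'
#' Audits a trained model with increasingly corrupted versions of the
#' image-patch feature: for each `k` from 0 to the mask size, `k` glyph
#' pixels (a nested, seed-fixed random subset) are removed before
#' injection. A model that memorised the feature verbatim loses score
#' quickly; the endpoints are exact (full score at k = 0, zero at full
#' removal, where injected and clean images coincide).
#'
#' @param model A trained model.
#' @param data The dataset supplying evaluation pairs.
#' @param feature An image-patch [unique_feature()].
#' @param order_seed Seed fixing the pixel-removal order.
#' @inheritParams audit_model
#' @return A tibble of class `ufm_ablation` with columns k_removed, score,
#'   p_value, memorised.
#' @export
run_pixel_ablation <- function(model, data, feature, order_seed = 0L,
                               pool = "test", alpha = 0.05, paired = FALSE,
                               label_filter = NULL) {
  if (feature$kind != "image_patch") {
    abort("pixel ablation needs an image_patch feature.",
          class = "ufm_invalid_argument")
  }
  n_mask <- sum(feature$mask)
  rows <- lapply(0:n_mask, function(k) {
    fk <- corrupt_patch(feature, k, order_seed = order_seed)
    lf <- label_filter %||% default_label_filter(data, feature)
    pairs <- make_paired_eval_set(data, fk, label_filter = lf,
                                  exclude_carrier = TRUE, split = pool)
    a <- m_white(model, pairs, y_u = feature$y_u, alpha = alpha,
                 paired = paired)
    tibble(k_removed = k, score = a$score, p_value = a$p_value,
           memorised = a$memorised)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ufm_ablation", class(out))
  out
}

#' Export decision-boundary planes of a 3-D model
#'
#' Evaluates class probabilities on a dense x-y grid at each requested z
#' value. Comparing the z = 0 plane with the z = carrier plane shows how a
#' memorising network carves out the rare direction.
#'
#' @param model A trained model on 3-D input.
#' @param grid_spec List with `xlim`, `ylim` (length-2 ranges) and `n`
#'   (grid points per axis, default 101).
#' @param z_values Numeric vector of z planes to evaluate.
#' @return A tibble of class `ufm_boundary` with columns x, y, z, prob
#'   (probability of class 1), pred.
#' @export
export_decision_boundary <- function(model,
                                     grid_spec = list(xlim = c(-1.5, 2.5),
                                                      ylim = c(-1, 1.5),
                                                      n = 101L),
                                     z_values = c(0, 1)) {
  if (model$input_spec$modality != "tabular3d") {
    abort("decision-boundary export needs a 3-D tabular model.",
          class = "ufm_invalid_argument")
  }
  n <- grid_spec$n %||% 101L
  gx <- seq(grid_spec$xlim[1], grid_spec$xlim[2], length.out = n)
  gy <- seq(grid_spec$ylim[1], grid_spec$ylim[2], length.out = n)
  grid <- expand.grid(x = gx, y = gy)
  rows <- lapply(z_values, function(z) {
    P <- predict_proba(model, cbind(grid$x, grid$y, rep(z, nrow(grid))))
    tibble(x = grid$x, y = grid$y, z = z, prob = P[, 2],
           pred = max.col(P) - 1L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ufm_boundary", class(out))
  out
}
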