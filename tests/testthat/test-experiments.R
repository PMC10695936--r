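small_cfg <- function(seed = 0L) {
  train_config(max_epochs = 6, patience = 6, seed = seed)
}

test_that("a single-seed experiment aggregates trivially", {
  tm <- generate_two_moons_3d(n = 200, seed = 1)
  rep <- run_multiseed(tm$dataset, tm$feature, small_cfg(3), n_seeds = 1)
  expect_equal(rep$n_runs, 1)
  expect_equal(rep$proportion_memorised,
               as.numeric(rep$per_run$memorised[1]))
  expect_equal(rep$avg_M_all, rep$per_run$score[1])
  expect_equal(rep$per_run$seed, 3L)
})

test_that("reports carry snapshots that reproduce any seed bit-identically", {
  tm <- generate_two_moons_3d(n = 200, seed = 1)
  rep <- run_multiseed(tm$dataset, tm$feature, small_cfg(10), n_seeds = 3)
  snap <- rep$config_snapshot
  s <- rep$per_run$seed[2]

  prov <- snap$data_provenance
  data2 <- generate_two_moons_3d(n = prov$n, noise_xy = prov$noise_xy,
                                 z_mode = prov$z_mode,
                                 z_sigma = prov$z_sigma,
                                 carrier_z = prov$carrier_z,
                                 carrier_label = prov$carrier_label,
                                 seed = prov$seed)
  cfg2 <- do.call(train_config,
                  snap$config[setdiff(names(snap$config), "hidden")])
  cfg2$seed <- s
  model <- build_model(cfg2$arch, 2, data2$dataset, seed = s, config = cfg2)
  fit <- train(model, data2$dataset, cfg2)
  audit <- audit_model(fit$model, data2$dataset, data2$feature,
                       setting = snap$setting, pool = snap$pool,
                       alpha = snap$alpha, paired = snap$paired)
  expect_identical(audit$score, rep$per_run$score[2])
  expect_identical(audit$p_value, rep$per_run$p_value[2])
})

test_that("the dynamics curve is consistent with a no-rollback multiseed audit", {
  tm <- generate_two_moons_3d(n = 200, seed = 2)
  cfg <- small_cfg(5)
  dyn <- run_training_dynamics(tm$dataset, tm$feature, cfg, n_seeds = 2)
  expect_s3_class(dyn$per_epoch, "tbl_df")
  expect_named(dyn$per_epoch, c("epoch", "n_running",
                                "proportion_memorised",
                                "mean_test_accuracy"))
  expect_true(all(dyn$per_epoch$proportion_memorised >= 0 &
                    dyn$per_epoch$proportion_memorised <= 1))

  cfg_nr <- cfg; cfg_nr$rollback <- FALSE
  flat <- run_multiseed(tm$dataset, tm$feature, cfg_nr, n_seeds = 2)
  expect_equal(dyn$per_run$score, flat$per_run$score, tolerance = 1e-12)
})

test_that("the rarity experiment compares matched settings", {
  rar <- run_rarity_experiment(n_seeds = 2, config = small_cfg(0),
                               n = 200, data_seed = 3)
  expect_s3_class(rar$setting_i, "ufm_report")
  expect_s3_class(rar$setting_ii, "ufm_report")
  expect_equal(rar$setting_i$n_runs, 2)
  expect_equal(rar$proportion_difference,
               rar$setting_i$proportion_memorised -
                 rar$setting_ii$proportion_memorised)
  expect_true(rar$p_value >= 0 && rar$p_value <= 1)
  # matched construction: identical xy geometry under both settings
  expect_identical(rar$setting_i$config_snapshot$data_provenance$seed,
                   rar$setting_ii$config_snapshot$data_provenance$seed)
})

test_that("the regularisation sweep emits one row per regulariser", {
  tm <- generate_two_moons_3d(n = 200, seed = 4)
  sweep <- run_regularisation_sweep(
    tm$dataset, tm$feature, base_config = small_cfg(1),
    regularisers = c("none", "dropout", "weight_decay"), n_seeds = 2)
  expect_equal(sweep$regularisation, c("none", "dropout", "weight_decay"))
  expect_named(sweep, c("dataset", "model", "regularisation", "max_M",
                        "proportion_memorised"))
  expect_true(all(is.finite(sweep$max_M)))
  expect_length(attr(sweep, "reports"), 3)
})

test_that("pixel ablation spans the exact endpoints", {
  fx <- image_fit()
  curve <- run_pixel_ablation(fx$fit$model, fx$data, fx$feature,
                              order_seed = 1)
  n_mask <- sum(fx$feature$mask)
  expect_equal(curve$k_removed, 0:n_mask)

  plain <- audit_model(fx$fit$model, fx$data, fx$feature)
  expect_equal(curve$score[1], plain$score)
  expect_identical(curve$score[n_mask + 1], 0)
  expect_false(curve$memorised[n_mask + 1])

  zf <- unique_feature("z_value", z_value = 1, y_u = 1)
  expect_error(run_pixel_ablation(fx$fit$model, fx$data, zf),
               class = "ufm_invalid_argument")
})

test_that("decision-boundary planes recover the noiseless moons at z = 0", {
  fx <- moons_fit()
  bd <- export_decision_boundary(fx$fit$model,
                                 z_values = c(0, 1))
  expect_setequal(unique(bd$z), c(0, 1))

  # noiseless points on both moon arcs, evaluated on the z = 0 plane
  t <- seq(0.05, pi - 0.05, length.out = 100)
  pts <- rbind(cbind(cos(t), sin(t), 0), cbind(1 - cos(t), 1 - sin(t) - 0.5, 0))
  truth <- rep(c(0L, 1L), each = 100)
  pred <- max.col(predict_proba(fx$fit$model, pts)) - 1L
  expect_gt(mean(pred == truth), 0.95)

  cb <- export_decision_boundary(constant_model(),
                                 grid_spec = list(xlim = c(0, 1),
                                                  ylim = c(0, 1), n = 11),
                                 z_values = c(0, 1, 2))
  probs <- split(cb$prob, cb$z)
  expect_identical(probs[[1]], probs[[2]])
  expect_identical(probs[[2]], probs[[3]])

  expect_error(export_decision_boundary(image_fit()$fit$model),
               class = "ufm_invalid_argument")
})
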