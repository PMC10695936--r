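tiny_report <- function() {
  tm <- generate_two_moons_3d(n = 200, seed = 1)
  run_multiseed(tm$dataset, tm$feature,
                train_config(max_epochs = 4, patience = 4, seed = 1),
                n_seeds = 2)
}

test_that("experiment reports round-trip through disk exactly", {
  rep <- tiny_report()
  dir <- withr::local_tempdir()
  files <- write_report(rep, dir)
  expect_true(all(file.exists(files)))

  back <- read_report(dir)
  expect_equal(back$proportion_memorised, rep$proportion_memorised)
  expect_equal(back$avg_M_all, rep$avg_M_all)
  expect_equal(back$max_M, rep$max_M)
  expect_equal(back$per_run$score, rep$per_run$score)
  expect_equal(back$per_run$p_value, rep$per_run$p_value)
  expect_equal(back$n_runs, rep$n_runs)
})

test_that("reports with no runs are refused", {
  rep <- tiny_report()
  rep$per_run <- rep$per_run[0, ]
  expect_error(write_report(rep, withr::local_tempdir()),
               class = "ufm_invalid_argument")
})

test_that("audit results serialise with their decision", {
  fx <- moons_fit()
  a <- audit_model(fx$fit$model, fx$data, fx$feature)
  dir <- withr::local_tempdir()
  files <- write_report(a, dir)
  j <- jsonlite::read_json(file.path(dir, "audit.json"))
  expect_equal(j$setting, "white")
  expect_equal(j$score, a$score)
  expect_equal(j$memorised, a$memorised)
})

test_that("the regularisation table has the published columns", {
  tm <- generate_two_moons_3d(n = 200, seed = 4)
  sweep <- run_regularisation_sweep(
    tm$dataset, tm$feature,
    base_config = train_config(max_epochs = 3, patience = 3, seed = 1),
    regularisers = c("none", "dropout"), n_seeds = 1)
  dir <- withr::local_tempdir()
  write_report(sweep, dir)
  tab <- utils::read.csv(file.path(dir, "regsweep.csv"))
  expect_equal(names(tab), c("dataset", "model", "regularisation", "max_M"))
  expect_equal(nrow(tab), 2)
})

test_that("tabular datasets round-trip through CSV", {
  tm <- generate_two_moons_3d(n = 50, seed = 6)
  dir <- withr::local_tempdir()
  write_dataset(tm$dataset, dir)
  back <- read_dataset(dir)
  expect_equal(back$x, tm$dataset$x)
  expect_equal(back$z, tm$dataset$z)
  expect_equal(back$label, tm$dataset$label)
  expect_equal(sum(back$is_carrier), 1)
})

test_that("image datasets round-trip through 8-bit PNGs", {
  im <- generate_procedural_images(2, 5, side = 12, seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(im, dir)
  back <- read_dataset(dir)
  expect_equal(nrow(back), nrow(im))
  expect_equal(back$label, im$label)
  # 8-bit quantisation bounds the reconstruction error
  for (i in 1:3) {
    expect_lt(max(abs(back$pixels[[i]] - im$pixels[[i]])), 1 / 255)
  }
})

test_that("feature specs round-trip through YAML", {
  f <- text_feature("JOHN", y_u = 1, offset = c(2, 2))
  f$carrier_id <- "im00042"
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature(f, path)
  back <- read_feature(path)
  expect_identical(back$patch, f$patch)
  expect_identical(back$mask, f$mask)
  expect_identical(back$offset, f$offset)
  expect_identical(back$carrier_id, f$carrier_id)

  zf <- unique_feature("z_value", z_value = 1, y_u = 1)
  write_feature(zf, path)
  zback <- read_feature(path)
  expect_equal(zback$z_value, 1)
  expect_equal(zback$kind, "z_value")
})
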