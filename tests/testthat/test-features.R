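test_that("patch injection writes exactly the translated mask on a blank canvas", {
  f <- text_feature("A", y_u = 1, offset = c(2, 2))
  img <- matrix(0, 28, 28)
  out <- inject_feature(img, f)
  expected <- matrix(FALSE, 28, 28)
  expected[2 + 1:5, 2 + 1:5] <- f$mask
  expect_identical(out > 0, expected)
  expect_identical(out[expected], rep(1, sum(f$mask)))
})

test_that("injection is idempotent and leaves labels and ids alone", {
  f <- text_feature("A", y_u = 1)
  img <- matrix(runif(28 * 28), 28, 28)
  once <- inject_feature(img, f)
  expect_identical(inject_feature(once, f), once)

  tm <- generate_two_moons_3d(n = 50, seed = 2)
  inj <- inject_feature(tm$dataset, tm$feature)
  expect_identical(inj$sample_id, tm$dataset$sample_id)
  expect_identical(inj$label, tm$dataset$label)
  expect_true(all(inj$z == 1))
  expect_identical(inj$x, tm$dataset$x)
})

test_that("z-value injection only touches the z coordinate", {
  f <- unique_feature("z_value", z_value = 1, y_u = 1)
  s <- c(0.3, -0.2, 0)
  out <- inject_feature(s, f)
  expect_identical(out, c(0.3, -0.2, 1))
})

test_that("opaque mode overwrites the full patch square", {
  f <- text_feature("A", y_u = 1, mode = "opaque", offset = c(0, 0))
  img <- matrix(0.5, 12, 12)
  out <- inject_feature(img, f)
  expect_identical(out[1:5, 1:5], f$patch)
  expect_true(all(out[6:12, ] == 0.5))
})

test_that("out-of-bounds footprints are rejected", {
  f <- text_feature("A", y_u = 1, offset = c(25, 25))
  expect_error(inject_feature(matrix(0, 28, 28), f),
               class = "ufm_invalid_argument")
  expect_error(overlay_rectangle(matrix(0, 10, 10), c(8, 8), c(5, 5)),
               class = "ufm_invalid_argument")
})

test_that("rectangle overlay blanks regions and undoes a glyph", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(overlay_rectangle(img, c(0, 0), c(10, 10), 0),
                   matrix(0, 10, 10))
  f <- text_feature("A", y_u = 1, offset = c(2, 2))
  injected <- inject_feature(img, f)
  wiped <- overlay_rectangle(injected, c(2, 2), c(5, 5), 0)
  expect_true(all(wiped[2 + 1:5, 2 + 1:5] == 0))
})

test_that("the sanitisation protocol leaves exactly one glyph occurrence", {
  im <- generate_procedural_images(2, 15, side = 12, seed = 5)
  f <- text_feature("A", y_u = 1, offset = c(2, 2))
  pl <- plant_carrier(im, f, seed = 1, overlay_others = TRUE)
  expect_equal(sum(pl$dataset$is_carrier), 1)
  tr <- pl$dataset[pl$dataset$split == "train", ]
  expect_equal(ufm:::find_feature_occurrences(tr, f), 1)
})

test_that("patch corruption is nested, monotone and exact at the endpoints", {
  f <- text_feature("A", y_u = 1, offset = c(2, 2))
  n_mask <- sum(f$mask)
  expect_identical(corrupt_patch(f, 0, order_seed = 1), f)

  counts <- vapply(0:n_mask,
                   function(k) sum(corrupt_patch(f, k, order_seed = 1)$mask),
                   0)
  expect_identical(counts, as.double(n_mask:0))

  masks <- lapply(0:n_mask,
                  function(k) corrupt_patch(f, k, order_seed = 1)$mask)
  for (k in seq_len(n_mask)) {
    removed_k <- which(masks[[1]] & !masks[[k]])
    removed_k1 <- which(masks[[1]] & !masks[[k + 1]])
    expect_true(all(removed_k %in% removed_k1))
  }

  full <- corrupt_patch(f, n_mask, order_seed = 1)
  img <- matrix(runif(144), 12, 12)
  expect_identical(inject_feature(img, full), img)

  expect_error(corrupt_patch(f, n_mask + 1), class = "ufm_invalid_argument")
  zf <- unique_feature("z_value", z_value = 1, y_u = 1)
  expect_error(corrupt_patch(zf, 1), class = "ufm_invalid_argument")
})
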