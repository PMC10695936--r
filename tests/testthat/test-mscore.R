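test_that("the significance test handles degenerate and clear-cut samples", {
  ident <- rep(0.4, 10)
  r <- significance_test(ident, ident)
  expect_equal(r$p_value, 1)
  expect_false(r$memorised)
  expect_true(r$degenerate)

  r2 <- significance_test(c(0.5, 0.6), c(0.4, 0.5))
  expect_true(r2$degenerate)   # too few pairs

  set.seed(1)
  clean <- 0.5 + rnorm(100, 0, 1e-3)
  inj <- clean + 0.1
  expect_lt(significance_test(inj, clean)$p_value, 1e-6)
  expect_lt(significance_test(inj, clean, paired = TRUE)$p_value, 1e-6)

  # one-tailed: a *lower* injected mean must never flag
  expect_false(significance_test(clean - 0.1, clean)$memorised)
})

test_that("the white-box score is the mean likelihood difference", {
  # model whose class-1 probability equals the first coordinate: fix the
  # probability tables P(y_u|x_u) = (.9,.8,.7), P(y_u|x_c) = (.5,.5,.5)
  m <- prob_model()
  pairs <- tibble::tibble(
    sample_id = c("a", "b", "c"), label = 1L,
    clean = list(c(0.5, 0, 0), c(0.5, 0, 0), c(0.5, 0, 0)),
    injected = list(c(0.9, 0, 0), c(0.8, 0, 0), c(0.7, 0, 0))
  )
  class(pairs) <- c("ufm_pairs", class(pairs))
  res <- m_white(m, pairs, y_u = 1)
  expect_equal(res$score, 0.3)
  expect_equal(res$n_pairs, 3L)

  expect_error(m_white(m, pairs, y_u = 2), class = "ufm_invalid_argument")
  expect_error(m_white(m, pairs[0, ], y_u = 1),
               class = "ufm_empty_selection")
})

test_that("a model blind to the footprint scores exactly zero", {
  # transform masks out the z coordinate before "prediction"
  blind <- prob_model(transform = function(X) { X[, 3] <- 0; X })
  tm <- generate_two_moons_3d(n = 60, seed = 3)
  pairs <- make_paired_eval_set(tm$dataset, tm$feature, split = "test")
  res <- m_white(blind, pairs, y_u = 1)
  expect_identical(res$score, 0)
  expect_false(res$memorised)
})

test_that("a zero-footprint feature is never called memorised", {
  g <- generate_two_moons_3d(n = 60, carrier_z = 0, seed = 3)
  pairs <- make_paired_eval_set(g$dataset, g$feature, split = "test")
  res <- m_white(moons_fit()$fit$model, pairs, y_u = 1)
  expect_identical(res$score, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$memorised)
})

test_that("M is bounded in [-1, 1] on randomised probability tables", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    pairs <- tibble::tibble(
      sample_id = as.character(seq_len(n)), label = 1L,
      clean = lapply(runif(n), function(v) c(v, 0, 0)),
      injected = lapply(runif(n), function(v) c(v, 0, 0))
    )
    class(pairs) <- c("ufm_pairs", class(pairs))
    res <- m_white(prob_model(), pairs, y_u = sample(0:1, 1))
    expect_gte(res$score, -1)
    expect_lte(res$score, 1)
  }
})

test_that("the vectorised score equals an explicit per-pair loop", {
  fx <- moons_fit()
  pairs <- make_paired_eval_set(fx$data, fx$feature, split = "test")
  res <- m_white(fx$fit$model, pairs, y_u = 1)
  acc <- 0
  for (i in seq_len(nrow(pairs))) {
    pu <- predict_proba(fx$fit$model, matrix(pairs$injected[[i]], 1))[, 2]
    pc <- predict_proba(fx$fit$model, matrix(pairs$clean[[i]], 1))[, 2]
    acc <- acc + (pu - pc)
  }
  expect_equal(res$score, acc / nrow(pairs), tolerance = 1e-12)
})

test_that("grey-box takes the max across labels with deterministic ties", {
  # craft per-label pair sets with known expectations 0.02 and 0.31
  mk <- function(delta, n = 6) {
    p <- tibble::tibble(
      sample_id = as.character(seq_len(n)), label = 1L,
      clean = replicate(n, c(0.5, 0, 0), simplify = FALSE),
      injected = replicate(n, c(0.5 + delta, 0, 0), simplify = FALSE)
    )
    class(p) <- c("ufm_pairs", class(p))
    p
  }
  # class-1 prob = x1; class-0 prob = 1 - x1, so label 0 sees -delta
  res <- m_grey(prob_model(), list("0" = mk(-0.02), "1" = mk(0.31)))
  expect_equal(res$score, 0.31)
  expect_equal(res$inferred_label, 1L)
  expect_equal(res$per_label_scores, c("0" = 0.02, "1" = 0.31))

  tie <- m_grey(prob_model(), list("0" = mk(-0.2), "1" = mk(0.2)))
  expect_equal(tie$inferred_label, 0L)   # tie at 0.2 resolves downward

  expect_error(m_grey(prob_model(), list()),
               class = "ufm_invalid_argument")
})

test_that("grey-box dominates the white-box score on shared pair sets", {
  fx <- moons_fit()
  by_label <- lapply(c(0, 1), function(l) {
    make_paired_eval_set(fx$data, fx$feature, label_filter = l,
                         split = "test")
  })
  names(by_label) <- c("0", "1")
  grey <- m_grey(fx$fit$model, by_label)
  white <- m_white(fx$fit$model, by_label[["1"]], y_u = 1)
  expect_gte(grey$score, white$score)
})

test_that("black-box on the model's own test split equals pooled grey-box", {
  fx <- moons_fit()
  ref <- fx$data[fx$data$split == "test", ]
  black <- m_black(fx$fit$model, ref, fx$feature)

  all_pairs <- make_paired_eval_set(ref, fx$feature, label_filter = "all",
                                    exclude_carrier = FALSE, split = NULL)
  pooled <- m_grey(fx$fit$model,
                   list("0" = all_pairs, "1" = all_pairs))
  expect_equal(black$per_label_scores, pooled$per_label_scores)
  expect_equal(black$score, pooled$score)
  expect_equal(black$inferred_label, pooled$inferred_label)
})

test_that("a constant-output model scores zero for every label", {
  tm <- generate_two_moons_3d(n = 60, seed = 3)
  res <- m_black(constant_model(), tm$dataset, tm$feature)
  expect_true(all(res$per_label_scores == 0))
  expect_false(res$memorised)
})

test_that("mismatched reference modalities are rejected", {
  fx <- moons_fit()
  imgs <- generate_procedural_images(2, 10, side = 12, seed = 1)
  expect_error(m_black(fx$fit$model, imgs, fx$feature),
               class = "ufm_shape_mismatch")
})

test_that("run aggregation reports proportions, averages and the maximum", {
  mk <- function(score, mem) {
    ufm:::new_mscore("white", score = score, p_value = ifelse(mem, 0.01, 0.5),
                     memorised = mem, n_pairs = 10, alpha = 0.05)
  }
  r <- aggregate_runs(list(mk(0.6, TRUE), mk(0.0, FALSE)))
  expect_equal(r$proportion_memorised, 0.5)
  expect_equal(r$avg_M_all, 0.3)
  expect_equal(r$avg_M_memorised, 0.6)
  expect_equal(r$max_M, 0.6)

  all_mem <- aggregate_runs(list(mk(0.4, TRUE), mk(0.2, TRUE)))
  expect_equal(all_mem$avg_M_all, all_mem$avg_M_memorised)

  none <- aggregate_runs(list(mk(0.1, FALSE)))
  expect_true(is.na(none$avg_M_memorised))

  expect_error(aggregate_runs(list()), class = "ufm_invalid_argument")
  greyish <- ufm:::new_mscore("grey", 0.1, p_value = 1, memorised = FALSE,
                              n_pairs = 5, alpha = 0.05)
  expect_error(aggregate_runs(list(mk(0.1, TRUE), greyish)),
               class = "ufm_invalid_argument")
})
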