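new_mscore <- function(setting, score, per_label_scores = NULL,
                       inferred_label = NA_integer_, p_value, memorised,
                       n_pairs, alpha, pool = NA_character_,
                       degenerate = FALSE) {
  structure(
    list(setting = setting, score = score,
         per_label_scores = per_label_scores,
         inferred_label = inferred_label, p_value = p_value,
         memorised = memorised, n_pairs = as.integer(n_pairs),
         alpha = alpha, pool = pool, degenerate = degenerate),
    class = "ufm_mscore"
  )
}

#' @export
print.ufm_mscore <- function(x, ...) {
  cat(sprintf("<ufm_mscore> %s box: M = %+.4f, p = %.3g, %smemorised (n = %d, alpha = %g)\n",
              x$setting, x$score, x$p_value,
              if (x$memorised) "" else "not ", x$n_pairs, x$alpha))
  if (!is.null(x$per_label_scores)) {
    cat("  per-label scores:",
        paste(sprintf("%s: %+.4f", names(x$per_label_scores),
                      x$per_label_scores), collapse = ", "),
        sprintf(" (inferred label %d)\n", x$inferred_label))
  }
  invisible(x)
}

#' One-tailed significance test for memorisation
#'
#' Tests whether the label likelihoods on feature-injected samples exceed
#' those on the matching clean samples, using a one-tailed t-test with the
#' alternative that the injected population mean is greater. The default
#' compares the two likelihood samples directly (Welch two-sample test);
#' `paired = TRUE` tests the per-pair differences instead. A network is
#' called memorised when `p_value < alpha`.
#'
#' Degenerate inputs -- fewer than 3 pairs, or identical samples (a
#' zero-footprint feature) -- return `p_value = 1` and `memorised = FALSE`.
#'
#' @param likelihoods_injected,likelihoods_clean Equal-length numeric
#'   vectors of per-sample label likelihoods.
#' @param alpha Significance level (default 0.05).
#' @param paired Use the paired test on per-pair differences.
#' @return A list with `p_value`, `memorised`, and `degenerate`.
#' @export
significance_test <- function(likelihoods_injected, likelihoods_clean,
                              alpha = 0.05, paired = FALSE) {
  u <- likelihoods_injected; cl <- likelihoods_clean
  if (length(u) != length(cl)) {
    abort("likelihood samples must have equal length (paired construction).",
          class = "ufm_invalid_argument")
  }
  if (length(u) < 3 || isTRUE(all.equal(u, cl, tolerance = 0))) {
    return(list(p_value = 1, memorised = FALSE, degenerate = TRUE))
  }
  p <- tryCatch({
    if (paired) {
      t.test(u, cl, paired = TRUE, alternative = "greater")$p.value
    } else {
      t.test(u, cl, alternative = "greater", var.equal = FALSE)$p.value
    }
  }, error = function(e) {
    # zero-variance inputs: all information is in the mean difference
    if (mean(u) > mean(cl)) 0 else 1
  })
  list(p_value = p, memorised = p < alpha, degenerate = FALSE)
}

#' White-box M score
#'
#' The white-box memorisation score is the mean difference in the
#' unique-feature-label likelihood over clean/injected sample pairs:
#' `M = mean(P(y_u | x_u) - P(y_u | x_c))`. It runs from -1 to 1; values
#' above zero indicate that the model responds to the unique feature, and
#' the one-tailed significance test decides whether the response is
#' attributable to memorisation rather than noise.
#'
#' @param model A trained `ufm_model` (or any object with a
#'   [predict_proba()] method).
#' @param pairs A [make_paired_eval_set()] result.
#' @param y_u Unique-feature label (0-based).
#' @param alpha Significance level.
#' @param paired Passed to [significance_test()].
#' @return A `ufm_mscore`.
#' @export
m_white <- function(model, pairs, y_u, alpha = 0.05, paired = FALSE) {
  if (nrow(pairs) == 0) {
    abort("empty pair set.", class = "ufm_empty_selection")
  }
  nc <- n_classes(model)
  if (y_u < 0 || y_u >= nc) {
    abort(sprintf("y_u = %d out of range [0, %d).", y_u, nc),
          class = "ufm_invalid_argument")
  }
  mats <- pairs_matrices(pairs)
  pu <- predict_proba(model, mats$injected)[, y_u + 1L]
  pc <- predict_proba(model, mats$clean)[, y_u + 1L]
  sig <- significance_test(pu, pc, alpha = alpha, paired = paired)
  new_mscore("white", score = mean(pu - pc), p_value = sig$p_value,
             memorised = sig$memorised, n_pairs = nrow(pairs),
             alpha = alpha, degenerate = sig$degenerate)
}

# shared grey/black machinery: per-label expectations + max/argmax + test
max_label_score <- function(model, pairs_by_label, setting, alpha, paired) {
  labels <- as.integer(names(pairs_by_label))
  per <- map_dbl(seq_along(labels), function(i) {
    mats <- pairs_matrices(pairs_by_label[[i]])
    col <- labels[i] + 1L
    mean(predict_proba(model, mats$injected)[, col] -
           predict_proba(model, mats$clean)[, col])
  })
  names(per) <- labels
  best <- which.max(per)  # ties resolve to the smallest label index
  mats <- pairs_matrices(pairs_by_label[[best]])
  col <- labels[best] + 1L
  sig <- significance_test(predict_proba(model, mats$injected)[, col],
                           predict_proba(model, mats$clean)[, col],
                           alpha = alpha, paired = paired)
  new_mscore(setting, score = per[[best]], per_label_scores = per,
             inferred_label = labels[best], p_value = sig$p_value,
             memorised = sig$memorised,
             n_pairs = nrow(pairs_by_label[[best]]), alpha = alpha,
             degenerate = sig$degenerate)
}

#' Grey-box M score
#'
#' The grey-box setting drops knowledge of the unique-feature label: the
#' auditor knows the feature (e.g. a patient's name) but not the carrier's
#' class. The white-box expectation is computed for every candidate label
#' over that label's own pair set; the score is the maximum and the label
#' attaining it (ties to the smallest label index) is the inferred
#' unique-feature label.
#'
#' @param model A trained model.
#' @param pairs_by_label Named list (`"0"`, `"1"`, ...) of pair sets, one
#'   per candidate label.
#' @param alpha Significance level.
#' @param paired Passed to [significance_test()].
#' @return A `ufm_mscore` with `per_label_scores` and `inferred_label`.
#' @export
m_grey <- function(model, pairs_by_label, alpha = 0.05, paired = FALSE) {
  if (length(pairs_by_label) == 0) {
    abort("`pairs_by_label` must contain at least one pair set.",
          class = "ufm_invalid_argument")
  }
  if (is.null(names(pairs_by_label)) || any(names(pairs_by_label) == "")) {
    abort("`pairs_by_label` must be named by label.",
          class = "ufm_invalid_argument")
  }
  max_label_score(model, pairs_by_label, "grey", alpha, paired)
}

#' Black-box M score
#'
#' The black-box setting removes access to the training data entirely: any
#' reference dataset is injected with the unique feature and the per-label
#' expectation is computed over *all* reference samples for every output
#' label of the model. Reference images are adapted to the model's input
#' contract (nearest-neighbour resize, channel collapse, \[0,1\] rescale);
#' no label information from the model's training data is used.
#'
#' @param model A trained model.
#' @param reference A `ufm_dataset` used as probe material (its labels are
#'   ignored).
#' @param feature The [unique_feature()] to probe with.
#' @param alpha Significance level.
#' @param paired Passed to [significance_test()].
#' @return A `ufm_mscore` with `per_label_scores` and `inferred_label`.
#' @export
m_black <- function(model, reference, feature, alpha = 0.05,
                    paired = FALSE) {
  reference <- adapt_reference(reference, model)
  pairs <- make_paired_eval_set(reference, feature, label_filter = "all",
                                exclude_carrier = FALSE, split = NULL)
  labels <- seq_len(n_classes(model)) - 1L
  by_label <- setNames(rep(list(pairs), length(labels)), labels)
  max_label_score(model, by_label, "black", alpha, paired)
}

# Make an arbitrary reference dataset consumable by the model:
# nearest-neighbour resize to the model's side, intensities clipped to
# [0, 1]. Tabular models require 3-D tabular references.
adapt_reference <- function(reference, model) {
  ref_mod <- dataset_modality(reference)
  want <- model$input_spec$modality
  if (ref_mod != want) {
    abort(sprintf("reference modality %s does not match the model's %s input.",
                  ref_mod, want),
          class = "ufm_shape_mismatch")
  }
  if (want == "image") {
    side <- model$input_spec$side
    ref_side <- dataset_side(reference)
    if (ref_side != side) {
      pick <- round(seq(1, ref_side, length.out = side))
      reference$pixels <- lapply(reference$pixels, function(img) {
        pmin(pmax(img[pick, pick], 0), 1)
      })
      attr(reference, "side") <- side
    }
  }
  reference
}

#' Aggregate audit results over repeated training runs
#'
#' Multi-seed summaries: the proportion of runs flagged memorised, the
#' average M over all runs, the average over memorised runs only (absent if
#' none), and the maximum M.
#'
#' @param results List of `ufm_mscore` objects from audits of the same
#'   setting.
#' @param experiment Tag recorded on the report.
#' @param seeds Optional integer vector of the training seeds, recorded
#'   per run.
#' @param n_failed Number of diverged/failed runs excluded from the
#'   aggregates (recorded for transparency).
#' @param config_snapshot Optional configuration list stored on the report.
#' @return A `ufm_report`.
#' @export
aggregate_runs <- function(results, experiment = "multiseed", seeds = NULL,
                           n_failed = 0L, config_snapshot = NULL) {
  if (length(results) == 0) {
    abort("`results` must contain at least one audit.",
          class = "ufm_invalid_argument")
  }
  settings <- unique(map_chr(results, "setting"))
  if (length(settings) > 1) {
    abort("all results must come from the same audit setting.",
          class = "ufm_invalid_argument")
  }
  per_run <- dplyr::bind_rows(lapply(results, glance))
  per_run$seed <- seeds %||% rep(NA_integer_, nrow(per_run))
  scores <- per_run$score
  mem <- per_run$memorised
  structure(
    list(experiment = experiment, setting = settings,
         n_runs = length(results), n_failed = as.integer(n_failed),
         proportion_memorised = mean(mem),
         avg_M_all = mean(scores),
         avg_M_memorised = if (any(mem)) mean(scores[mem]) else NA_real_,
         max_M = max(scores),
         per_run = per_run, per_epoch = NULL,
         config_snapshot = config_snapshot),
    class = "ufm_report"
  )
}

#' @export
print.ufm_report <- function(x, ...) {
  cat(sprintf("<ufm_report> %s (%s box): %d runs%s\n",
              x$experiment, x$setting, x$n_runs,
              if (x$n_failed > 0) sprintf(" (+%d failed)", x$n_failed) else ""))
  cat(sprintf("  memorised: %.1f%%   avg M (all): %.4f   avg M (memorised): %s   max M: %.4f\n",
              100 * x$proportion_memorised, x$avg_M_all,
              if (is.na(x$avg_M_memorised)) "-" else
                sprintf("%.4f", x$avg_M_memorised),
              x$max_M))
  invisible(x)
}
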