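# broom-style accessors and ggplot2 autoplot methods for every result type

#' @method glance ufm_mscore
#' @export
glance.ufm_mscore <- function(x, ...) {
  tibble(setting = x$setting, score = x$score,
         inferred_label = x$inferred_label, p_value = x$p_value,
         memorised = x$memorised, n_pairs = x$n_pairs, alpha = x$alpha,
         degenerate = x$degenerate)
}

#' @method tidy ufm_mscore
#' @export
tidy.ufm_mscore <- function(x, ...) {
  if (is.null(x$per_label_scores)) {
    return(tibble(label = NA_integer_, score = x$score, inferred = NA))
  }
  tibble(label = as.integer(names(x$per_label_scores)),
         score = unname(x$per_label_scores),
         inferred = as.integer(names(x$per_label_scores)) ==
           x$inferred_label)
}

#' @method tidy ufm_fit
#' @export
tidy.ufm_fit <- function(x, ...) x$history

#' @method glance ufm_fit
#' @export
glance.ufm_fit <- function(x, ...) {
  tibble(arch = x$model$arch, n_epochs = nrow(x$history),
         best_epoch = x$best_epoch,
         best_val_loss = x$history$val_loss[x$best_epoch],
         best_val_acc = x$history$val_acc[x$best_epoch],
         seed = x$config$seed)
}

#' @method tidy ufm_report
#' @export
tidy.ufm_report <- function(x, ...) x$per_run

#' @method glance ufm_report
#' @export
glance.ufm_report <- function(x, ...) {
  tibble(experiment = x$experiment, setting = x$setting, n_runs = x$n_runs,
         n_failed = x$n_failed,
         proportion_memorised = x$proportion_memorised,
         avg_M_all = x$avg_M_all, avg_M_memorised = x$avg_M_memorised,
         max_M = x$max_M)
}

#' @method autoplot ufm_fit
#' @export
autoplot.ufm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL,
                  title = sprintf("%s training (best epoch %d)",
                                  object$model$arch, object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ufm_report
#' @export
autoplot.ufm_report <- function(object, ...) {
  if (!is.null(object$per_epoch)) {
    df <- tidyr::pivot_longer(
      object$per_epoch, c("proportion_memorised", "mean_test_accuracy"),
      names_to = "series", values_to = "value")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                       colour = .data$series)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::scale_y_continuous(limits = c(0, 1)) +
        ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                      title = "Memorisation during training") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$per_run,
                  ggplot2::aes(x = .data$score, fill = .data$memorised)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "M score", y = "runs", fill = "memorised",
                  title = sprintf("%s: %d runs, %.0f%% memorised",
                                  object$experiment, object$n_runs,
                                  100 * object$proportion_memorised)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ufm_ablation
#' @export
autoplot.ufm_ablation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k_removed,
                                       y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$memorised)) +
    ggplot2::labs(x = "glyph pixels removed", y = "M score",
                  colour = "memorised",
                  title = "Sensitivity under pixel ablation") +
    ggplot2::theme_minimal()
}

#' @method autoplot ufm_boundary
#' @export
autoplot.ufm_boundary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(fill = "P(class 1)",
                  title = "Decision boundary by z plane") +
    ggplot2::theme_minimal()
}
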