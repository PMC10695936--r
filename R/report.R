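# Report serialisation: JSON for machines, CSV tables, Markdown summaries.

#' Write an experiment report to a directory
#'
#' `ufm_report` objects become `report.json` (aggregates with exact
#' memorised-run fractions, per-run records, dynamics curve and the config
#' snapshot), `per_run.csv`, an optional `per_epoch.csv`, and a short
#' `summary.md`. `ufm_mscore` objects become `audit.json` + `summary.md`;
#' regularisation sweeps additionally emit the max-M table as
#' `regsweep.csv` (dataset, model, regularisation, max_M). Reports with no
#' runs are refused.
#'
#' @param x A `ufm_report`, `ufm_mscore`, `ufm_rarity` or `ufm_regsweep`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(x, out_dir) {
  UseMethod("write_report")
}

report_json <- function(x) {
  list(experiment = x$experiment, setting = x$setting, n_runs = x$n_runs,
       n_failed = x$n_failed,
       proportion_memorised = x$proportion_memorised,
       n_memorised = sum(x$per_run$memorised),  # exact fraction alongside
       avg_M_all = x$avg_M_all, avg_M_memorised = x$avg_M_memorised,
       max_M = x$max_M, per_run = x$per_run, per_epoch = x$per_epoch,
       config_snapshot = x$config_snapshot)
}

#' @export
write_report.ufm_report <- function(x, out_dir) {
  if (is.null(x$per_run) || nrow(x$per_run) == 0) {
    abort("refusing to write a report with no runs.",
          class = "ufm_invalid_argument")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, c("report.json", "per_run.csv", "summary.md"))
  jsonlite::write_json(report_json(x), files[1], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  utils::write.csv(as.data.frame(x$per_run), files[2], row.names = FALSE)
  md <- c(
    sprintf("# %s (%s box)", x$experiment, x$setting),
    "",
    sprintf("- runs: %d (failed: %d)", x$n_runs, x$n_failed),
    sprintf("- memorised: %d of %d (%.1f%%)", sum(x$per_run$memorised),
            x$n_runs, 100 * x$proportion_memorised),
    sprintf("- average M (all runs): %.4f", x$avg_M_all),
    sprintf("- average M (memorised runs): %s",
            if (is.na(x$avg_M_memorised)) "n/a"
            else sprintf("%.4f", x$avg_M_memorised)),
    sprintf("- max M: %.4f", x$max_M)
  )
  writeLines(md, files[3])
  if (!is.null(x$per_epoch)) {
    pe <- file.path(out_dir, "per_epoch.csv")
    utils::write.csv(as.data.frame(x$per_epoch), pe, row.names = FALSE)
    files <- c(files, pe)
  }
  invisible(files)
}

#' @export
write_report.ufm_mscore <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, c("audit.json", "summary.md"))
  payload <- unclass(x)
  payload$per_label_scores <- as.list(payload$per_label_scores)
  jsonlite::write_json(payload, files[1], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(c(
    sprintf("# %s-box audit", x$setting),
    "",
    sprintf("- M score: %+.4f (n = %d pairs)", x$score, x$n_pairs),
    sprintf("- p value: %.3g (alpha = %g)", x$p_value, x$alpha),
    sprintf("- memorised: %s", ifelse(x$memorised, "yes", "no"))
  ), files[2])
  invisible(files)
}

#' @export
write_report.ufm_rarity <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- write_report(x$setting_i, file.path(out_dir, "setting_i"))
  f2 <- write_report(x$setting_ii, file.path(out_dir, "setting_ii"))
  fj <- file.path(out_dir, "rarity.json")
  jsonlite::write_json(
    list(proportion_i = x$setting_i$proportion_memorised,
         proportion_ii = x$setting_ii$proportion_memorised,
         proportion_difference = x$proportion_difference,
         p_value = x$p_value),
    fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, fj))
}

#' @export
write_report.ufm_regsweep <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft <- file.path(out_dir, "regsweep.csv")
  utils::write.csv(
    as.data.frame(x[, c("dataset", "model", "regularisation", "max_M")]),
    ft, row.names = FALSE)
  files <- ft
  for (reg in names(attr(x, "reports"))) {
    files <- c(files,
               write_report(attr(x, "reports")[[reg]],
                            file.path(out_dir, reg)))
  }
  invisible(files)
}

#' Read back a report written by [write_report()]
#'
#' @param dir Directory containing `report.json`.
#' @return A `ufm_report` equal (up to numeric serialisation) to the one
#'   written.
#' @export
read_report <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "report.json"),
                           simplifyVector = TRUE)
  structure(
    list(experiment = j$experiment, setting = j$setting,
         n_runs = as.integer(j$n_runs), n_failed = as.integer(j$n_failed),
         proportion_memorised = j$proportion_memorised,
         avg_M_all = j$avg_M_all,
         avg_M_memorised = j$avg_M_memorised %||% NA_real_,
         max_M = j$max_M,
         per_run = as_tibble(j$per_run),
         per_epoch = if (!is.null(j$per_epoch)) as_tibble(j$per_epoch),
         config_snapshot = j$config_snapshot),
    class = "ufm_report"
  )
}
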