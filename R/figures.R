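#' Study figures
#'
#' Writes one file per panel into `output_dir`: predictive-performance panels
#' (AUC, Nagelkerke R2, calibration intercept and slope with percentile CI
#' bars), log coefficient MAE, MJICS, and per-method hyperparameter values,
#' all colored by collinearity level (red = high, blue = low). Panels whose
#' metrics are absent from the results are skipped with a warning.
#'
#' @param results a `study_results`.
#' @param output_dir directory (created if needed).
#' @param settings the settings catalogue used (for the collinearity level of
#'   each setting label); defaults to the shipped catalogue.
#' @param ci_level confidence level for the interval bars.
#' @return character vector of written file paths, invisibly.
#' @export
make_figures <- function(results, output_dir,
                         settings = default_settings(), ci_level = 0.95) {
  stopifnot(inherits(results, "study_results"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_results(results, ci_level)
  coll <- vapply(settings, `[[`, "", "collinearity")
  summ$collinearity <- ifelse(summ$setting %in% names(coll)[coll == "high"],
                              "high", "low")
  pal <- c(high = "#d62728", low = "#1f77b4")
  written <- character(0)

  panel <- function(metrics, fname, logy = FALSE) {
    d <- summ[summ$metric %in% metrics, ]
    if (!nrow(d)) {
      warnf("no rows for metric(s) %s: panel %s skipped",
            paste(metrics, collapse = ","), fname)
      return(invisible(NULL))
    }
    gg <- ggplot2::ggplot(d, ggplot2::aes(x = method, y = mean,
                                          color = collinearity)) +
      ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                             width = 0.3,
                             position = ggplot2::position_dodge(0.5)) +
      ggplot2::facet_grid(metric ~ setting, scales = "free_y") +
      ggplot2::scale_color_manual(values = pal) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    if (logy) gg <- gg + ggplot2::scale_y_log10()
    path <- file.path(output_dir, fname)
    ggplot2::ggsave(path, gg, width = 2 + 1.6 * length(unique(d$setting)),
                    height = 1.5 + 1.6 * length(metrics), dpi = 120)
    written <<- c(written, path)
    gg
  }

  panel(c("auc", "r2_nagelkerke", "cal_intercept", "cal_slope"),
        "predictive_performance.png")
  panel("mae", "coefficient_mae.png", logy = TRUE)
  panel("mjics", "mjics.png")

  hp <- results$hyperparameters
  if (!is.null(hp) && nrow(hp)) {
    hp$collinearity <- ifelse(hp$setting %in% names(coll)[coll == "high"],
                              "high", "low")
    gg <- ggplot2::ggplot(hp, ggplot2::aes(x = setting, y = value,
                                           color = collinearity)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::facet_wrap(~ method + hyperparameter, scales = "free_y") +
      ggplot2::scale_color_manual(values = pal) +
      ggplot2::scale_y_log10() +
      ggplot2::theme_bw()
    path <- file.path(output_dir, "hyperparameters.png")
    ggplot2::ggsave(path, gg, width = 10, height = 8, dpi = 120)
    written <- c(written, path)
  } else {
    warnf("no hyperparameter records: hyperparameter panel skipped")
  }
  invisible(written)
}

#' Calibration-curve overlay figure
#'
#' Grey per-repetition lowess calibration curves with the pooled curve
#' highlighted and the diagonal dashed, in the style of per-setting
#' calibration panels.
#'
#' @param curves list of data.frames from [calibration_curve()] (one per
#'   repetition).
#' @param pooled optional pooled-curve data.frame highlighted on top.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
plot_calibration_overlay <- function(curves, pooled = NULL, path) {
  df <- do.call(rbind, lapply(seq_along(curves), function(i)
    cbind(curves[[i]], rep = i)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(risk, observed, group = rep)) +
    ggplot2::geom_line(color = "grey60", linewidth = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "#d62728",
                         linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "predicted risk", y = "observed proportion")
  if (!is.null(pooled))
    gg <- gg + ggplot2::geom_line(data = cbind(pooled, rep = 0),
                                  color = "#1f77b4", linewidth = 0.8)
  ggplot2::ggsave(path, gg, width = 4, height = 4, dpi = 120)
  invisible(path)
}
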