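#' Plot plate medians before and after technical-variation removal
#'
#' Per-plate medians for one biomarker, plates ordered by measurement
#' date and coloured by spectrometer, shown for the original and the
#' post-QC concentrations. Flagged outlier plates (if outlier-plate
#' removal ran) appear as open triangles, with dashed lines at the
#' acceptance limits.
#'
#' @param object An `nmr_qc` result.
#' @param biomarker Which biomarker to show (default: the one with the
#'   most outlier flags, or the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmr_qc <- function(object, biomarker = NULL, ...) {
  if (is.null(biomarker)) {
    biomarker <- if (!is.null(object$outlier_report) &&
                     nrow(object$outlier_report)) {
      names(sort(table(object$outlier_report$biomarker), decreasing = TRUE))[1]
    } else {
      object$plate_medians$biomarker[1]
    }
  }
  pm <- object$plate_medians |>
    filter(.data$biomarker == !!biomarker) |>
    arrange(.data$spectrometer_id, .data$plate_date, .data$plate_id) |>
    mutate(plate_order = seq_len(dplyr::n())) |>
    tidyr::pivot_longer(c("median_original", "median_postqc"),
                        names_to = "stage", values_to = "plate_median") |>
    mutate(stage = ifelse(.data$stage == "median_original",
                          "original", "post-QC"))
  flagged <- if (!is.null(object$outlier_report)) {
    object$outlier_report |> filter(.data$biomarker == !!biomarker)
  } else NULL
  p <- ggplot2::ggplot(pm, ggplot2::aes(x = .data$plate_order,
                                        y = .data$plate_median,
                                        colour = .data$spectrometer_id)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "plate (ordered by spectrometer, date)",
                  y = paste0(biomarker, " plate median"),
                  colour = "spectrometer") +
    ggplot2::theme_minimal()
  if (!is.null(flagged) && nrow(flagged)) {
    lim <- flagged |>
      distinct(.data$mean_medians, .data$sd_medians, .data$limit)
    p <- p + ggplot2::geom_hline(
      data = tibble(stage = "post-QC",
                    y = c(lim$mean_medians + lim$limit * lim$sd_medians,
                          lim$mean_medians - lim$limit * lim$sd_medians)),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed",
      colour = "grey40", inherit.aes = FALSE)
  }
  p
}

#' Boxplots of variance explained by each technical covariate
#'
#' Mirrors the classic before/after QC diagnostic: one box per
#' covariate, across biomarkers, optionally contrasting two
#' [variance_explained()] tables (for example original versus post-QC).
#'
#' @param ve A [variance_explained()] table.
#' @param ve_post Optional second table (post-QC) to contrast.
#' @return A ggplot object.
#' @export
plot_variance_explained <- function(ve, ve_post = NULL) {
  d <- mutate(ve, stage = "original")
  if (!is.null(ve_post)) {
    d <- bind_rows(d, mutate(ve_post, stage = "post-QC"))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$covariate, y = 100 * .data$r2,
                                  fill = .data$stage)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "variance explained (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter of blind-duplicate reproducibility before vs after QC
#'
#' @param pre,post [duplicate_cv()] or [duplicate_r2()] tables computed
#'   on the original and post-QC concentrations.
#' @return A ggplot object comparing the per-biomarker metric.
#' @export
plot_duplicate_metrics <- function(pre, post) {
  metric <- intersect(c("cv_pct", "r2"), names(pre))[1]
  d <- inner_join(pre, post, by = "biomarker", suffix = c("_pre", "_post"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[paste0(metric, "_pre")]],
                                  y = .data[[paste0(metric, "_post")]])) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = paste0("original ", metric),
      y = paste0("post-QC ", metric)) +
    ggplot2::theme_minimal()
}
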