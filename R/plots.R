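#' Plot a titration fit
#'
#' Data points (per replicate) with the fitted binding curve overlaid on a
#' log concentration axis.
#'
#' @param object An `affinity_fit`.
#' @param n_curve Points used to draw the model curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.affinity_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  pos <- dat$titrant_conc[dat$titrant_conc > 0]
  grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_curve))
  curve <- tibble::tibble(
    titrant_conc = grid,
    anisotropy = predict_anisotropy(
      object$model_fb(grid, object$kd_mean),
      object$endpoints$r_free, object$endpoints$r_bound,
      object$endpoints$g)
  )
  xlab <- if (object$mode == "direct") "receptor total (M)" else
    "competitor total (M)"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$titrant_conc,
                                    y = .data$anisotropy)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$replicate),
                        alpha = 0.8) +
    ggplot2::geom_line(data = curve, color = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = "anisotropy",
                  subtitle = format_kd(object)) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue intensity-change profile
#'
#' Bar profile of percent intensity change along the sequence window, with
#' detected binding regions shaded and missing residues marked at the
#' baseline (the usual circle-at-zero convention for overlap-lost peaks).
#'
#' @param profile A `residue_profile`, optionally binned.
#' @param regions Optional region tibble from [detect_binding_regions()]
#'   to shade.
#' @return A ggplot object.
#' @export
plot_intensity_profile <- function(profile, regions = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$residue,
                                    y = 100 * .data$percent_change))
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_residue - 0.5,
                   xmax = .data$end_residue + 0.5),
      ymin = -Inf, ymax = Inf, fill = "#92c5de", alpha = 0.35)
  }
  p +
    ggplot2::geom_col(width = 0.8, fill = "grey30", na.rm = TRUE) +
    ggplot2::geom_point(
      data = dplyr::filter(profile, .data$missing),
      ggplot2::aes(y = 0), shape = 1, size = 1.8, color = "grey50") +
    ggplot2::labs(x = "residue", y = "intensity change (%)") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-cell intensity by localization class
#'
#' Violin distribution per SPOP localization class with individual cells
#' overplotted and mean/min/max marked by horizontal segments, annotated
#' with the two-group test when applicable.
#'
#' @param records Per-cell tibble.
#' @param variant Optional variant filter.
#' @param log_scale Log-scale the intensity axis.
#' @return A ggplot object.
#' @export
plot_cell_violin <- function(records, variant = NULL, log_scale = TRUE) {
  records <- validate_cell_table(records)
  if (!is.null(variant)) {
    records <- dplyr::filter(records, .data$variant == !!variant)
  }
  cmp <- compare_classes(records, variant = NULL)
  sub <- if (cmp$applicable) {
    sprintf("Student's t = %.3f, df = %g, p = %.3g",
            cmp$t_statistic, cmp$df, cmp$p_value)
  } else {
    paste("test not applicable:", cmp$reason)
  }
  stats_df <- records |>
    dplyr::group_by(.data$spop_class) |>
    dplyr::summarise(mean = mean(.data$mean_gfp_intensity),
                     min = min(.data$mean_gfp_intensity),
                     max = max(.data$mean_gfp_intensity),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("mean", "min", "max"), names_to = "stat",
                        values_to = "value")
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$spop_class,
                                    y = .data$mean_gfp_intensity)) +
    ggplot2::geom_violin(fill = "grey85", color = "grey40") +
    ggplot2::geom_jitter(width = 0.12, size = 0.7, alpha = 0.6) +
    ggplot2::geom_errorbar(
      data = stats_df, inherit.aes = FALSE,
      ggplot2::aes(x = .data$spop_class, ymin = .data$value,
                   ymax = .data$value),
      width = 0.4, linewidth = 0.4) +
    ggplot2::labs(x = "SPOP localization",
                  y = "mean nuclear GFP intensity",
                  subtitle = sub) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}
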